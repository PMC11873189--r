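// Multi-head scaled-dot-product attention kernels.
// Dense projections, layer norms and feed-forward stay in R (BLAS-bound);
// only the per-sample, per-head score/softmax/mix loops live here, where
// interpreter overhead would otherwise dominate at clinical batch sizes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Q, K, V: (B*L) x d matrices, rows grouped by sample; pad: length B*L.
// Returns O (B*L x d) and the attention tensor A (L x L x B*H), head-major
// within sample: slice index = (b-1)*H + h.
// [[Rcpp::export(name = ".attn_forward")]]
List attn_forward(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  const LogicalVector& pad, int B, int L, int H) {
  const int d = Q.n_cols;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat O(B * L, d, arma::fill::zeros);
  arma::cube A(L, L, B * H, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    std::vector<int> padc;
    for (int j = 0; j < L; ++j) if (pad[r0 + j]) padc.push_back(j);
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dh;
      arma::mat Qh = Q.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      arma::mat Kh = K.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      arma::mat S = Qh * Kh.t() * scale;
      for (size_t m = 0; m < padc.size(); ++m) S.col(padc[m]).fill(-arma::datum::inf);
      // row softmax
      for (int i = 0; i < L; ++i) {
        arma::rowvec row = S.row(i);
        double mx = row.max();
        row = arma::exp(row - mx);
        S.row(i) = row / arma::accu(row);
      }
      A.slice(b * H + h) = S;
      O.submat(r0, c0, r0 + L - 1, c0 + dh - 1) =
        S * V.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
    }
  }
  return List::create(Named("O") = O, Named("A") = A);
}

// Backward pass: given dO and the cached forward tensors, produce dQ, dK, dV.
// [[Rcpp::export(name = ".attn_backward")]]
List attn_backward(const arma::mat& dO, const arma::cube& A,
                   const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                   int B, int L, int H) {
  const int d = Q.n_cols;
  const int dh = d / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(B * L, d, arma::fill::zeros);
  arma::mat dK(B * L, d, arma::fill::zeros);
  arma::mat dV(B * L, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * L;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dh;
      const arma::mat& Ah = A.slice(b * H + h);
      arma::mat dOh = dO.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      arma::mat Vh = V.submat(r0, c0, r0 + L - 1, c0 + dh - 1);
      dV.submat(r0, c0, r0 + L - 1, c0 + dh - 1) = Ah.t() * dOh;
      arma::mat dA = dOh * Vh.t();
      arma::colvec rs = arma::sum(dA % Ah, 1);
      arma::mat dS = Ah % (dA.each_col() - rs);
      dQ.submat(r0, c0, r0 + L - 1, c0 + dh - 1) =
        dS * K.submat(r0, c0, r0 + L - 1, c0 + dh - 1) * scale;
      dK.submat(r0, c0, r0 + L - 1, c0 + dh - 1) =
        dS.t() * Q.submat(r0, c0, r0 + L - 1, c0 + dh - 1) * scale;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK, Named("dV") = dV);
}
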