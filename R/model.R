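#' Model hyperparameter configuration
#'
#' @param vocab_size total token vocabulary size (features + 3 reserved).
#' @param max_len max input length L including the TASK slot.
#' @param d_k embedding dimension (default 128); must be divisible by
#'   `n_heads`.
#' @param n_layers number of encoder blocks.
#' @param n_heads attention heads.
#' @param ff_dim width of the position-wise feed-forward layer
#'   (default `4 * d_k`).
#' @param dropout dropout rate applied to the attention output and the
#'   feed-forward output during training.
#' @param sigma smoothing temperature of the sigmoid concordance loss.
#' @return object of class `ct_config`.
#' @export
ct_config <- function(vocab_size, max_len, d_k = 128L, n_layers = 4L,
                      n_heads = 4L, ff_dim = 4L * d_k, dropout = 0.1,
                      sigma = 0.1) {
  if (d_k %% n_heads != 0L) stopf("d_k (%d) must be divisible by n_heads (%d)", d_k, n_heads)
  structure(list(vocab_size = as.integer(vocab_size), max_len = as.integer(max_len),
                 d_k = as.integer(d_k), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
                 dropout = dropout, sigma = sigma),
            class = "ct_config")
}

# truncated-normal initializer (clipped at 2 sd), std 0.02
trunc_normal <- function(n, sd = 0.02) {
  qn <- stats::qnorm(stats::runif(n, stats::pnorm(-2), stats::pnorm(2)))
  qn * sd
}

#' Initialize model parameters
#'
#' Weight matrices are truncated-normal (sd 0.02); layer-norm gains start at
#' 1, all biases and the survival head at 0 (a zero head gives score 0 for
#' every patient until the first update).
#'
#' @param config a [ct_config()].
#' @param seed RNG seed for reproducible initialization.
#' @return named list of parameter arrays (class `ct_params`).
#' @export
ct_init <- function(config, seed = NULL) {
  d <- config$d_k; ff <- config$ff_dim; V <- config$vocab_size
  Vf <- V - 3L  # feature-name classes for the masked-name head
  with_seed(seed, {
    p <- list(
      Emb = matrix(trunc_normal(V * d), V, d),
      w_val = trunc_normal(d),
      w_surv = rep(0, d),
      W_name = matrix(trunc_normal(d * Vf), d, Vf),
      b_name = rep(0, Vf),
      w_valh = trunc_normal(d),
      b_valh = 0
    )
    for (l in seq_len(config$n_layers)) {
      p[[paste0("Wq", l)]] <- matrix(trunc_normal(d * d), d, d)
      p[[paste0("Wk", l)]] <- matrix(trunc_normal(d * d), d, d)
      p[[paste0("Wv", l)]] <- matrix(trunc_normal(d * d), d, d)
      p[[paste0("Wo", l)]] <- matrix(trunc_normal(d * d), d, d)
      p[[paste0("ln1g", l)]] <- rep(1, d)
      p[[paste0("ln1b", l)]] <- rep(0, d)
      p[[paste0("W1", l)]] <- matrix(trunc_normal(d * ff), d, ff)
      p[[paste0("b1", l)]] <- rep(0, ff)
      p[[paste0("W2", l)]] <- matrix(trunc_normal(ff * d), ff, d)
      p[[paste0("b2", l)]] <- rep(0, d)
      p[[paste0("ln2g", l)]] <- rep(1, d)
      p[[paste0("ln2b", l)]] <- rep(0, d)
    }
    structure(p, class = "ct_params")
  })
}

#' Embed an encoded batch into input vectors
#'
#' `E = E_k + E_v`: a name-lookup embedding plus a linear projection of the
#' scalar value into d_k dimensions, with no positional term — the model is
#' order-free by construction.
#'
#' @param params model parameters ([ct_init()]).
#' @param batch an encoded batch ([encode_batch()]).
#' @return matrix `(B*L) x d_k`; rows are grouped by sample (sample 1
#'   positions 1..L, then sample 2, ...).
#' @export
embed_inputs <- function(params, batch) {
  idx <- as.vector(t(batch$token_ids))  # sample-major ordering
  if (any(idx < 1L) || any(idx > nrow(params$Emb))) stopf("token id out of vocabulary range")
  v <- as.vector(t(batch$values))
  params$Emb[idx, , drop = FALSE] + outer(v, params$w_val)
}

# row-wise layer normalization; returns normalized output and cache
layernorm_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = add_row(mul_row(xhat, g), b), xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- mul_row(dy, g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

#' Run the transformer encoder forward
#'
#' Post-norm encoder blocks: multi-head scaled-dot-product self-attention
#' (PAD columns masked out before the softmax), residual + layer norm,
#' position-wise feed-forward (ReLU), residual + layer norm. Returns the
#' final per-position embeddings; optionally the per-layer attention
#' matrices and the cache needed for backpropagation.
#'
#' @param params model parameters.
#' @param config a [ct_config()].
#' @param batch an encoded batch; `batch$pad` marks PAD positions.
#' @param train if `TRUE`, apply dropout (caller controls the RNG stream).
#' @param keep_cache keep intermediates for [ct_backward()].
#' @param return_attention return per-layer, per-head attention matrices.
#' @return list: `P` final embeddings `(B*L) x d_k`, `task_rows` row indices
#'   of the TASK position per sample, `B`, `L`, and optionally `cache`,
#'   `attention`.
#' @export
ct_forward <- function(params, config, batch, train = FALSE,
                       keep_cache = FALSE, return_attention = FALSE) {
  B <- nrow(batch$token_ids); L <- ncol(batch$token_ids)
  d <- config$d_k; H <- config$n_heads
  X <- embed_inputs(params, batch)
  if (any(!is.finite(X))) stopf("non-finite values in input embeddings")
  pad <- as.vector(t(batch$pad))
  drop_p <- if (train) config$dropout else 0
  cache <- if (keep_cache) list(batch = batch, pad = pad, X0 = X,
                                layers = vector("list", config$n_layers)) else NULL
  attn_out_all <- if (return_attention) vector("list", config$n_layers) else NULL

  for (l in seq_len(config$n_layers)) {
    Wq <- params[[paste0("Wq", l)]]; Wk <- params[[paste0("Wk", l)]]
    Wv <- params[[paste0("Wv", l)]]; Wo <- params[[paste0("Wo", l)]]
    Q <- X %*% Wq; K <- X %*% Wk; Vm <- X %*% Wv
    att <- .attn_forward(Q, K, Vm, pad, B, L, H)
    O <- att$O; A_cube <- att$A
    attn <- O %*% Wo
    dm1 <- NULL
    if (drop_p > 0) {
      dm1 <- matrix(stats::runif(length(attn)) >= drop_p, nrow(attn)) / (1 - drop_p)
      attn <- attn * dm1
    }
    ln1 <- layernorm_fwd(X + attn, params[[paste0("ln1g", l)]], params[[paste0("ln1b", l)]])
    X1 <- ln1$y
    Hpre <- add_row(X1 %*% params[[paste0("W1", l)]], params[[paste0("b1", l)]])
    Hact <- Hpre * (Hpre > 0)
    F2 <- add_row(Hact %*% params[[paste0("W2", l)]], params[[paste0("b2", l)]])
    dm2 <- NULL
    if (drop_p > 0) {
      dm2 <- matrix(stats::runif(length(F2)) >= drop_p, nrow(F2)) / (1 - drop_p)
      F2 <- F2 * dm2
    }
    ln2 <- layernorm_fwd(X1 + F2, params[[paste0("ln2g", l)]], params[[paste0("ln2b", l)]])
    Xout <- ln2$y
    if (any(!is.finite(Xout))) stopf("non-finite activations in encoder layer %d", l)
    if (keep_cache)
      cache$layers[[l]] <- list(Xin = X, Q = Q, K = K, Vm = Vm, A = A_cube,
                                O = O, dm1 = dm1, ln1 = ln1, X1 = X1,
                                relu_mask = Hpre > 0, Hact = Hact, dm2 = dm2,
                                ln2 = ln2)
    if (return_attention) attn_out_all[[l]] <- A_cube
    X <- Xout
  }
  out <- list(P = X, task_rows = (seq_len(B) - 1L) * L + 1L, B = B, L = L)
  if (keep_cache) out$cache <- cache
  if (return_attention) out$attention <- attn_out_all
  out
}

#' Survival prediction head
#'
#' A single linear neuron without bias on the TASK-position embedding:
#' `beta = P_task %*% w_surv`. Higher scores predict longer survival.
#' @param params model parameters.
#' @param P_task matrix B x d_k of TASK-position output embeddings.
#' @return numeric vector of survival scores.
#' @export
survival_head <- function(params, P_task) as.vector(P_task %*% params$w_surv)

#' Masked-prediction heads
#'
#' Per masked position: a softmax layer over the feature-name vocabulary and
#' a scalar linear value estimate.
#' @param params model parameters.
#' @param P_masked matrix (masked slots x d_k) of masked-position embeddings.
#' @return list `logits` (slots x feature classes), `probs`, `values`.
#' @export
masked_heads <- function(params, P_masked) {
  if (is.null(dim(P_masked))) P_masked <- matrix(P_masked, nrow = 1L)
  if (nrow(P_masked) == 0L) stopf("no masked positions")
  logits <- add_row(P_masked %*% params$W_name, params$b_name)
  list(logits = logits, probs = exp(log_softmax(logits)),
       values = as.vector(P_masked %*% params$w_valh + params$b_valh))
}

# zero-filled gradient container mirroring params
grad_zeros <- function(params) {
  g <- lapply(params, function(p) { p[] <- 0; p })
  class(g) <- "ct_params"
  g
}

#' Backpropagate through the encoder and embedding layer
#'
#' Given the gradient of a scalar loss with respect to the final embeddings
#' `P`, accumulates gradients for every encoder and embedding parameter into
#' `grads` (head gradients are handled by the training loops, which assemble
#' `dP`).
#'
#' @param params model parameters.
#' @param config a [ct_config()].
#' @param fwd result of `ct_forward(..., keep_cache = TRUE)`.
#' @param dP gradient `(B*L) x d_k` w.r.t. the final embeddings.
#' @param grads gradient container from `grad_zeros()` (modified copy
#'   returned).
#' @return updated `grads`.
#' @export
ct_backward <- function(params, config, fwd, dP, grads = grad_zeros(params)) {
  cache <- fwd$cache
  if (is.null(cache)) stopf("forward pass was run without keep_cache = TRUE")
  B <- fwd$B; L <- fwd$L; d <- config$d_k; H <- config$n_heads
  dX <- dP
  for (l in rev(seq_len(config$n_layers))) {
    lc <- cache$layers[[l]]
    g2 <- params[[paste0("ln2g", l)]]
    bk2 <- layernorm_bwd(dX, lc$ln2, g2)
    grads[[paste0("ln2g", l)]] <- grads[[paste0("ln2g", l)]] + bk2$dg
    grads[[paste0("ln2b", l)]] <- grads[[paste0("ln2b", l)]] + bk2$db
    dRes2 <- bk2$dx                      # gradient into (X1 + F2)
    dF2 <- if (is.null(lc$dm2)) dRes2 else dRes2 * lc$dm2
    grads[[paste0("b2", l)]] <- grads[[paste0("b2", l)]] + colSums(dF2)
    grads[[paste0("W2", l)]] <- grads[[paste0("W2", l)]] + crossprod(lc$Hact, dF2)
    dHact <- tcrossprod(dF2, params[[paste0("W2", l)]])
    dHpre <- dHact * lc$relu_mask
    grads[[paste0("b1", l)]] <- grads[[paste0("b1", l)]] + colSums(dHpre)
    grads[[paste0("W1", l)]] <- grads[[paste0("W1", l)]] + crossprod(lc$X1, dHpre)
    dX1 <- dRes2 + tcrossprod(dHpre, params[[paste0("W1", l)]])

    g1 <- params[[paste0("ln1g", l)]]
    bk1 <- layernorm_bwd(dX1, lc$ln1, g1)
    grads[[paste0("ln1g", l)]] <- grads[[paste0("ln1g", l)]] + bk1$dg
    grads[[paste0("ln1b", l)]] <- grads[[paste0("ln1b", l)]] + bk1$db
    dRes1 <- bk1$dx                      # gradient into (Xin + attn)
    dAttn <- if (is.null(lc$dm1)) dRes1 else dRes1 * lc$dm1
    grads[[paste0("Wo", l)]] <- grads[[paste0("Wo", l)]] + crossprod(lc$O, dAttn)
    dO <- tcrossprod(dAttn, params[[paste0("Wo", l)]])

    bk <- .attn_backward(dO, lc$A, lc$Q, lc$K, lc$Vm, B, L, H)
    dQ <- bk$dQ; dK <- bk$dK; dV <- bk$dV
    Xin <- lc$Xin
    grads[[paste0("Wq", l)]] <- grads[[paste0("Wq", l)]] + crossprod(Xin, dQ)
    grads[[paste0("Wk", l)]] <- grads[[paste0("Wk", l)]] + crossprod(Xin, dK)
    grads[[paste0("Wv", l)]] <- grads[[paste0("Wv", l)]] + crossprod(Xin, dV)
    dX <- dRes1 +
      tcrossprod(dQ, params[[paste0("Wq", l)]]) +
      tcrossprod(dK, params[[paste0("Wk", l)]]) +
      tcrossprod(dV, params[[paste0("Wv", l)]])
  }
  # embedding layer: dEmb by token id, dw_val from the value projection
  idx <- as.vector(t(cache$batch$token_ids))
  v <- as.vector(t(cache$batch$values))
  agg <- rowsum(dX, group = idx)
  gid <- as.integer(rownames(agg))
  grads$Emb[gid, ] <- grads$Emb[gid, , drop = FALSE] + agg
  grads$w_val <- grads$w_val + colSums(dX * v)
  grads
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory with the configuration and vocabulary as JSON
#' and the weights in R's native serialization; loading validates that the
#' weights match the stored configuration.
#'
#' @param model a `ct_model` (list with `params`, `config`, `vocab`).
#' @param dir checkpoint directory (created if needed).
#' @export
checkpoint_save <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  vocab_save(model$vocab, file.path(dir, "vocab.json"))
  saveRDS(model$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(ct_config, cfg[c("vocab_size", "max_len", "d_k", "n_layers",
                                     "n_heads", "ff_dim", "dropout", "sigma")])
  vocab <- vocab_load(file.path(dir, "vocab.json"))
  params <- readRDS(file.path(dir, "weights.rds"))
  if (nrow(params$Emb) != config$vocab_size || ncol(params$Emb) != config$d_k)
    stopf("checkpoint weights do not match its configuration")
  structure(list(params = params, config = config, vocab = vocab), class = "ct_model")
}
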