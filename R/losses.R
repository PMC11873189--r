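#' Sigmoid approximation of Harrell's concordance as a survival loss
#'
#' Differentiable surrogate of `1 - C` over the comparable pairs of a batch.
#' A pair (i, j) is comparable when patient i has an observed event
#' (`event[i] == 1`) and `time[i] < time[j]`. Each comparable pair contributes
#' `1 / (1 + exp((beta[j] - beta[i]) / sigma))`, and pair weights are uniform
#' over comparable pairs, so the loss lies in (0, 1): 0.5 when all scores are
#' equal, near 0 when every pair is ordered concordantly (higher score =
#' longer survival) with well-separated scores, near 1 when anti-ordered.
#'
#' @param beta numeric vector of predicted survival scores (higher = longer
#'   predicted survival).
#' @param time numeric vector of follow-up times (months).
#' @param event integer/numeric vector in \{0, 1\}; 1 = death observed.
#' @param sigma smoothing temperature of the sigmoid; smaller values approach
#'   the exact step function (and the exact concordance index) at the price of
#'   vanishing gradients.
#' @param gradient if `TRUE`, also return the analytic gradient d loss / d beta.
#' @return scalar loss, or `list(loss, grad)` when `gradient = TRUE`.
#' @seealso [c_index()]
#' @export
survival_loss <- function(beta, time, event, sigma = 0.1, gradient = FALSE) {
  n <- length(beta)
  stopifnot(length(time) == n, length(event) == n)
  cmp <- comparable_pairs(time, event)
  total <- sum(cmp)
  if (total == 0L)
    stop(structure(class = c("no_comparable_pairs", "error", "condition"),
                   list(message = "no comparable pairs in batch", call = sys.call())))
  w <- cmp / total
  # z[i, j] = (beta_j - beta_i) / sigma ; term = plogis(-z)
  z <- outer(beta, beta, function(bi, bj) (bj - bi) / sigma)
  term <- stats::plogis(-z)
  loss <- sum(w * term)
  if (!gradient) return(loss)
  # d term / d beta_i = term (1 - term) / sigma ; d/d beta_j = -that
  g <- w * term * (1 - term) / sigma
  grad <- rowSums(g) - colSums(g)
  list(loss = loss, grad = grad)
}

# indicator matrix of comparable pairs: event_i = 1 and T_i < T_j
comparable_pairs <- function(time, event) {
  cmp <- outer(time, time, `<`)
  cmp[event != 1, ] <- FALSE
  cmp
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs ordered correctly by the score. A pair (i, j)
#' is comparable when `event[i] == 1` and `time[i] < time[j]`; it is concordant
#' when `beta[i] < beta[j]` (the patient who lived longer got the higher
#' score), and tied scores earn half credit. Pairs with tied times are not
#' comparable.
#'
#' @inheritParams survival_loss
#' @return concordance in \[0, 1\]; 0.5 is chance level.
#' @export
c_index <- function(beta, time, event) {
  cmp <- comparable_pairs(time, event)
  total <- sum(cmp)
  if (total == 0L) stopf("c_index undefined: no comparable pairs")
  d <- outer(beta, beta, function(bi, bj) bj - bi)  # beta_j - beta_i
  conc <- sum(cmp & d > 0) + 0.5 * sum(cmp & d == 0)
  conc / total
}

#' Mask a fraction of feature names in an encoded row
#'
#' Replaces the names (token ids) of `ceiling(mask_fraction * n_features)`
#' randomly chosen non-special positions by the MASK token, leaving the values
#' untouched, as in masked-feature pretraining. TASK and PAD positions are
#' never masked.
#'
#' @param row encoded row: list with `token_ids`, `values`, `pad` (see
#'   [sample_and_pad()]).
#' @param vocab a [ct_vocab()] object.
#' @param mask_fraction fraction of feature names to mask (default 0.20).
#' @param seed optional integer seed for reproducible masking.
#' @return the row with masked `token_ids` plus a `targets` data.frame holding
#'   the position, original token id, and value of every masked slot.
#' @export
mask_features <- function(row, vocab, mask_fraction = 0.20, seed = NULL) {
  stopifnot(mask_fraction > 0, mask_fraction < 1)
  feat_pos <- which(!row$pad & row$token_ids != vocab$task_id)
  if (length(feat_pos) == 0L) stopf("row has no maskable features")
  k <- ceiling(mask_fraction * length(feat_pos))
  picked <- with_seed(seed, feat_pos[sample.int(length(feat_pos), k)])
  targets <- data.frame(position = picked,
                        token_id = row$token_ids[picked],
                        value = row$values[picked])
  row$token_ids[picked] <- vocab$mask_id
  row$targets <- targets
  row
}

#' Masked-pretraining loss
#'
#' Weighted sum of a categorical cross-entropy over masked feature names and a
#' mean squared error over masked feature values, each averaged over masked
#' slots: `alpha1 * CE + alpha2 * MSE`. Defaults `alpha1 = 1`, `alpha2 = 0.01`
#' weight name recovery far above value regression (masked values stay visible
#' in the input).
#'
#' @param name_logits matrix (masked slots x feature-vocabulary size) of
#'   unnormalized scores for the masked names.
#' @param value_estimates numeric vector of predicted values per masked slot.
#' @param target_class integer vector of true feature-class indices (1-based
#'   into the feature vocabulary).
#' @param target_value numeric vector of true values.
#' @param alpha1,alpha2 loss weights.
#' @return scalar loss.
#' @export
pretrain_loss <- function(name_logits, value_estimates, target_class,
                          target_value, alpha1 = 1, alpha2 = 0.01) {
  m <- length(target_class)
  stopifnot(m >= 1L, nrow(name_logits) == m, length(value_estimates) == m,
            length(target_value) == m)
  lp <- log_softmax(name_logits)
  ce <- -mean(lp[cbind(seq_len(m), target_class)])
  mse <- mean((value_estimates - target_value)^2)
  alpha1 * ce + alpha2 * mse
}

# numerically stable row-wise log softmax
log_softmax <- function(x) {
  m <- apply(x, 1L, max)
  x <- x - m
  x - log(rowSums(exp(x)))
}
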