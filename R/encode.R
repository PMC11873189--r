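#' Build the token vocabulary for a cohort
#'
#' Reserves distinct ids for the PAD, TASK (a.k.a. CLS) and MASK special
#' tokens, then assigns one id per feature name in stable (sorted) order.
#' Categorical codebooks travel with the vocabulary so a fine-tuned model
#' reuses the ids of its pretraining run.
#'
#' @param cohort a `ct_cohort`, or a character vector of feature names.
#' @return object of class `ct_vocab` with fields `pad_id`, `task_id`,
#'   `mask_id`, `feature_ids` (named integer vector), `size`, `n_reserved`,
#'   `codebooks`.
#' @export
ct_vocab <- function(cohort) {
  feats <- if (is.character(cohort)) cohort else colnames(cohort$tab)
  feats <- sort(unique(feats))
  cb <- if (is.character(cohort)) list() else cohort$schema$codebooks
  structure(list(pad_id = 1L, task_id = 2L, mask_id = 3L, n_reserved = 3L,
                 feature_ids = stats::setNames(seq_along(feats) + 3L, feats),
                 size = length(feats) + 3L, codebooks = cb),
            class = "ct_vocab")
}

#' @export
print.ct_vocab <- function(x, ...) {
  cat(sprintf("<ct_vocab> %d feature tokens + 3 reserved (PAD/TASK/MASK)\n",
              x$size - x$n_reserved))
  invisible(x)
}

#' Serialize / restore a vocabulary as JSON
#' @param vocab a `ct_vocab`.
#' @param path file path.
#' @export
vocab_save <- function(vocab, path) {
  v <- unclass(vocab)
  v$feature_ids <- as.list(v$feature_ids)     # keep names in JSON objects
  v$codebooks <- lapply(v$codebooks, as.list)
  jsonlite::write_json(v, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname vocab_save
#' @export
vocab_load <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = FALSE)
  v$feature_ids <- vapply(v$feature_ids, as.integer, integer(1))
  v$codebooks <- lapply(v$codebooks, function(cb) vapply(cb, as.integer, integer(1)))
  for (f in c("pad_id", "task_id", "mask_id", "n_reserved", "size")) v[[f]] <- as.integer(v[[f]])
  structure(v, class = "ct_vocab")
}

#' Choose the max input length from the feature-count distribution
#'
#' Computes the chosen percentile (linear interpolation between order
#' statistics, rounded up to an integer) of the per-patient non-missing
#' feature counts and adds 1 for the TASK slot. The default 95th percentile
#' keeps the input short for sparse cohorts while covering almost all
#' patients; the result never exceeds 1 + the number of unique features.
#'
#' @param cohort a `ct_cohort`.
#' @param percentile percentile in (0, 100].
#' @return integer max length L (including the TASK slot).
#' @export
compute_max_length <- function(cohort, percentile = 95) {
  if (!length(cohort$id)) stopf("cohort is empty")
  if (percentile <= 0 || percentile > 100) stopf("percentile must be in (0, 100]")
  q <- ceiling(pctl(feature_counts(cohort), percentile))
  min(1L + as.integer(q), 1L + ncol(cohort$tab))
}

#' Sample and pad one patient record into a fixed-length encoded row
#'
#' Position 1 is always the TASK token with value 1. The record's non-missing
#' features follow: when they fit within `L - 1` slots all are used, otherwise
#' `L - 1` of them are sampled uniformly without replacement (a fresh sample
#' per training iteration). Remaining slots are PAD with value 0 and are
#' excluded from attention and losses.
#'
#' @param record one element of [as_records()].
#' @param L max input length (>= 2), see [compute_max_length()].
#' @param vocab a [ct_vocab()].
#' @param shuffle if `TRUE` (training) sample feature order/subset randomly;
#'   if `FALSE` (inference) features are laid out in deterministic token-id
#'   order (truncation, if any, must be handled by the caller via seeds).
#' @param seed optional seed for the random sample.
#' @return list `token_ids`, `values`, `pad` — each of length `L`.
#' @export
sample_and_pad <- function(record, L, vocab, shuffle = TRUE, seed = NULL) {
  stopifnot(L >= 2L)
  ids <- unname(vocab$feature_ids[names(record$features)])
  if (anyNA(ids)) stopf("record contains feature(s) outside the vocabulary")
  vals <- unname(record$features)
  n <- length(ids)
  k <- min(n, L - 1L)
  if (n > 0L) {
    sel <- if (shuffle) with_seed(seed, sample.int(n, k)) else order(ids)[seq_len(k)]
    ids <- ids[sel]; vals <- vals[sel]
  }
  token_ids <- c(vocab$task_id, ids, rep(vocab$pad_id, L - 1L - k))
  values <- c(1, vals, rep(0, L - 1L - k))
  list(token_ids = as.integer(token_ids), values = as.numeric(values),
       pad = token_ids == vocab$pad_id)
}

#' Encode a set of records into a batch of fixed-length rows
#'
#' @param records list of records from [as_records()].
#' @inheritParams sample_and_pad
#' @return list of matrices `token_ids`, `values`, `pad` (batch x L).
#' @export
encode_batch <- function(records, L, vocab, shuffle = TRUE, seed = NULL) {
  B <- length(records)
  token_ids <- matrix(vocab$pad_id, B, L)
  values <- matrix(0, B, L)
  with_seed(seed, {
    for (b in seq_len(B)) {
      r <- sample_and_pad(records[[b]], L, vocab, shuffle = shuffle)
      token_ids[b, ] <- r$token_ids
      values[b, ] <- r$values
    }
  })
  list(token_ids = token_ids, values = values, pad = token_ids == vocab$pad_id)
}
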