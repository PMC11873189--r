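#' Random train/test split management
#'
#' Draws `n_splits` independent, stratification-free random partitions of the
#' cohort into train/test index sets.
#'
#' @param cohort a `ct_cohort`.
#' @param n_splits number of independent splits (default 10).
#' @param train_frac training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list of `list(train =, test =)` integer index pairs.
#' @export
make_splits <- function(cohort, n_splits = 10, train_frac = 0.8, seed = 1L) {
  n <- length(cohort$id)
  if (n < 10L) stopf("cohort too small to split (n = %d)", n)
  if (train_frac >= 1) warnf("train_frac >= 1: test sets will be empty")
  k <- min(n, max(1L, round(train_frac * n)))
  with_seed(seed, lapply(seq_len(n_splits), function(s) {
    tr <- sort(sample.int(n, k))
    list(train = tr, test = setdiff(seq_len(n), tr))
  }))
}

#' Serialize splits to JSON for exact reuse
#' @param splits result of [make_splits()].
#' @param path file path.
#' @export
splits_save <- function(splits, path) {
  jsonlite::write_json(splits, path, digits = NA)
  invisible(path)
}

#' @rdname splits_save
#' @export
splits_load <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = FALSE),
         function(s) list(train = as.integer(unlist(s$train)),
                          test = as.integer(unlist(s$test))))
}

# ---- Adam optimizer with global-norm gradient clipping ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) { p[] <- 0; p }),
       v = lapply(params, function(p) { p[] <- 0; p }),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 1.0, freeze = character(0)) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(clip) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (nm %in% freeze) next
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Masked-feature self-supervised pretraining
#'
#' Trains the encoder to recover randomly masked feature names (and values)
#' from the visible features, for a fixed number of optimizer steps. Both
#' loss components are logged. The resulting checkpoint warm-starts
#' [fine_tune()] (gradual learning when the fine-tuning cohort is the same,
#' transfer learning when it differs).
#'
#' @param cohort a `ct_cohort` (unlabeled use: outcomes are ignored).
#' @param config a [ct_config()]; built automatically when `NULL`.
#' @param iters optimizer steps.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param mask_fraction fraction of feature names masked per row.
#' @param alpha1,alpha2 pretraining loss weights (names / values).
#' @param length_percentile percentile for [compute_max_length()].
#' @param seed RNG seed (initialization, batching, masking, dropout).
#' @param verbose print progress every 500 steps.
#' @return a `ct_model` with a `history` data.frame (step, loss_names,
#'   loss_values).
#' @export
pretrain <- function(cohort, config = NULL, iters = 2000L, batch_size = 64L,
                     lr = 1e-3, mask_fraction = 0.20, alpha1 = 1, alpha2 = 0.01,
                     length_percentile = 95, seed = 1L, verbose = FALSE) {
  vocab <- ct_vocab(cohort)
  L <- compute_max_length(cohort, length_percentile)
  if (is.null(config)) config <- ct_config(vocab_size = vocab$size, max_len = L)
  records <- as_records(cohort)
  params <- ct_init(config, seed = seed)
  state <- adam_init(params)
  hist <- if (iters > 0) data.frame(step = seq_len(iters), loss_names = NA_real_,
                                    loss_values = NA_real_) else
    data.frame(step = integer(0), loss_names = numeric(0), loss_values = numeric(0))
  n <- length(records)
  with_seed(seed + 1L, {
    for (it in seq_len(iters)) {
      ids <- sample.int(n, min(batch_size, n))
      batch <- encode_batch(records[ids], config$max_len, vocab, shuffle = TRUE)
      masked <- mask_batch(batch, vocab, mask_fraction)
      step <- pretrain_step(params, config, masked, vocab, alpha1, alpha2)
      if (!is.finite(step$loss)) stopf("pretraining diverged (non-finite loss) at step %d", it)
      upd <- adam_step(params, step$grads, state, lr = lr,
                       freeze = "w_surv")
      params <- upd$params; state <- upd$state
      hist$loss_names[it] <- step$loss_names; hist$loss_values[it] <- step$loss_values
      if (verbose && it %% 500L == 0L)
        message(sprintf("pretrain step %d: names %.4f values %.4f", it,
                        step$loss_names, step$loss_values))
    }
  })
  structure(list(params = params, config = config, vocab = vocab,
                 history = hist), class = "ct_model")
}

# mask every row of an encoded batch; returns batch + flat target info
mask_batch <- function(batch, vocab, mask_fraction) {
  B <- nrow(batch$token_ids); L <- ncol(batch$token_ids)
  rows <- integer(0); pos <- integer(0); cls <- integer(0); val <- numeric(0)
  for (b in seq_len(B)) {
    row <- list(token_ids = batch$token_ids[b, ], values = batch$values[b, ],
                pad = batch$pad[b, ])
    m <- mask_features(row, vocab, mask_fraction)
    batch$token_ids[b, ] <- m$token_ids
    rows <- c(rows, rep(b, nrow(m$targets)))
    pos <- c(pos, m$targets$position)
    cls <- c(cls, m$targets$token_id - vocab$n_reserved)
    val <- c(val, m$targets$value)
  }
  list(batch = batch, rows = rows, pos = pos, class_idx = cls, value = val, L = L)
}

# one pretraining forward/backward; returns loss components and grads
pretrain_step <- function(params, config, masked, vocab, alpha1, alpha2) {
  fwd <- ct_forward(params, config, masked$batch, train = TRUE, keep_cache = TRUE)
  flat <- (masked$rows - 1L) * masked$L + masked$pos
  Pm <- fwd$P[flat, , drop = FALSE]
  heads <- masked_heads(params, Pm)
  m <- length(flat)
  lp <- log_softmax(heads$logits)
  loss_names <- -mean(lp[cbind(seq_len(m), masked$class_idx)])
  loss_values <- mean((heads$values - masked$value)^2)
  # head gradients
  dlogits <- exp(lp)
  dlogits[cbind(seq_len(m), masked$class_idx)] <-
    dlogits[cbind(seq_len(m), masked$class_idx)] - 1
  dlogits <- dlogits * (alpha1 / m)
  dvals <- 2 * (heads$values - masked$value) * (alpha2 / m)
  grads <- grad_zeros(params)
  grads$W_name <- crossprod(Pm, dlogits)
  grads$b_name <- colSums(dlogits)
  grads$w_valh <- colSums(Pm * dvals)
  grads$b_valh <- sum(dvals)
  dP <- matrix(0, nrow(fwd$P), config$d_k)
  dP[flat, ] <- tcrossprod(dlogits, params$W_name) + outer(dvals, params$w_valh)
  grads <- ct_backward(params, config, fwd, dP, grads)
  list(loss = alpha1 * loss_names + alpha2 * loss_values,
       loss_names = loss_names, loss_values = loss_values, grads = grads)
}

#' Fine-tune (or directly train) survival models over splits
#'
#' Optimizes the sigmoid-concordance survival loss on each training split,
#' starting either from a pretraining checkpoint (encoder warm start, fresh
#' zero-initialized survival head) or from random initialization (direct
#' learning). Per-epoch test concordance is recorded as a learning curve for
#' every split.
#'
#' @param cohort a `ct_cohort` with outcomes.
#' @param splits list from [make_splits()].
#' @param checkpoint optional `ct_model` from [pretrain()] (its vocabulary
#'   and configuration are reused and must cover the cohort's features).
#' @param config a [ct_config()] when training from scratch; defaults are
#'   built from the cohort.
#' @param epochs training epochs per split.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param sigma smoothing of the survival loss (overrides config when given).
#' @param length_percentile percentile for [compute_max_length()].
#' @param seed RNG seed.
#' @param d_k,n_layers,n_heads convenience overrides applied when `config`
#'   is `NULL`.
#' @param verbose print per-epoch progress.
#' @return list of class `ct_fit`: `models` (one `ct_model` per split),
#'   `curves` (data.frame split/epoch/c_index), `test_cindex` (final per
#'   split), `splits`.
#' @export
fine_tune <- function(cohort, splits, checkpoint = NULL, config = NULL,
                      epochs = 30L, batch_size = 64L, lr = 1e-3, sigma = NULL,
                      length_percentile = 95, seed = 1L,
                      d_k = 64L, n_layers = 2L, n_heads = 4L, verbose = FALSE) {
  if (!is.null(checkpoint)) {
    vocab <- checkpoint$vocab; config <- checkpoint$config
    unknown <- setdiff(colnames(cohort$tab), names(vocab$feature_ids))
    if (length(unknown)) stopf("cohort features absent from checkpoint vocabulary: %s",
                               paste(unknown, collapse = ", "))
  } else {
    vocab <- ct_vocab(cohort)
    if (is.null(config)) config <- ct_config(vocab$size,
                                             compute_max_length(cohort, length_percentile),
                                             d_k = d_k, n_layers = n_layers,
                                             n_heads = n_heads)
  }
  if (!is.null(sigma)) config$sigma <- sigma
  records <- as_records(cohort)
  curves <- list(); models <- list(); final_c <- numeric(length(splits))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    params <- if (is.null(checkpoint)) ct_init(config, seed = seed + s)
      else checkpoint$params
    params$w_surv <- rep(0, config$d_k)  # survival head always freshly initialized
    state <- adam_init(params)
    curve <- data.frame(split = integer(0), epoch = integer(0),
                        loss = numeric(0), c_index = numeric(0))
    with_seed(seed + 1000L * s, {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(length(sp$train))
        bs <- split(sp$train[ord], ceiling(seq_along(ord) / batch_size))
        ep_losses <- numeric(0)
        for (ids in bs) {
          if (length(ids) < 2L) next
          batch <- encode_batch(records[ids], config$max_len, vocab, shuffle = TRUE)
          fwd <- ct_forward(params, config, batch, train = TRUE, keep_cache = TRUE)
          beta <- survival_head(params, fwd$P[fwd$task_rows, , drop = FALSE])
          sl <- tryCatch(survival_loss(beta, cohort$time[ids], cohort$event[ids],
                                       sigma = config$sigma, gradient = TRUE),
                         no_comparable_pairs = function(e) NULL)
          if (is.null(sl)) next  # skip batches with no comparable pair
          ep_losses <- c(ep_losses, sl$loss)
          grads <- grad_zeros(params)
          grads$w_surv <- colSums(fwd$P[fwd$task_rows, , drop = FALSE] * sl$grad)
          dP <- matrix(0, nrow(fwd$P), config$d_k)
          dP[fwd$task_rows, ] <- outer(sl$grad, params$w_surv)
          grads <- ct_backward(params, config, fwd, dP, grads)
          upd <- adam_step(params, grads, state, lr = lr)
          params <- upd$params; state <- upd$state
        }
        model_s <- structure(list(params = params, config = config, vocab = vocab),
                             class = "ct_model")
        ci <- if (length(sp$test) >= 2L)
          tryCatch(c_index(predict_scores(model_s, cohort, idx = sp$test),
                           cohort$time[sp$test], cohort$event[sp$test]),
                   error = function(e) NA_real_)
          else NA_real_
        curve <- rbind(curve, data.frame(split = s, epoch = ep,
                                         loss = mean(ep_losses), c_index = ci))
        if (verbose) message(sprintf("split %d epoch %d: test C = %.3f", s, ep, ci))
      }
    })
    models[[s]] <- structure(list(params = params, config = config, vocab = vocab),
                             class = "ct_model")
    final_c[s] <- if (nrow(curve)) utils::tail(curve$c_index, 1L) else NA_real_
    curves[[s]] <- curve
  }
  structure(list(models = models, curves = do.call(rbind, curves),
                 test_cindex = final_c, splits = splits), class = "ct_fit")
}

#' Predict survival scores for a cohort
#'
#' Deterministic inference: when a patient's features fit within the model's
#' max length, all of them are used in a canonical order (the score is
#' order-invariant anyway); when they do not, the score is averaged over 20
#' seeded feature subsamples so repeated calls agree exactly.
#'
#' @param model a `ct_model`.
#' @param cohort a `ct_cohort` encoded with the model's vocabulary.
#' @param idx optional patient indices (default all).
#' @param n_subsamples number of seeded subsamples used for patients whose
#'   feature count exceeds the max length.
#' @return numeric vector of survival scores beta (higher = longer predicted
#'   survival).
#' @export
predict_scores <- function(model, cohort, idx = NULL, n_subsamples = 20L) {
  if (is.null(idx)) idx <- seq_along(cohort$id)
  records <- as_records(cohort)[idx]
  config <- model$config; vocab <- model$vocab; L <- config$max_len
  counts <- vapply(records, function(r) length(r$features), integer(1))
  beta <- numeric(length(records))
  fits <- counts <= L - 1L
  if (any(fits)) {
    batch <- encode_batch(records[fits], L, vocab, shuffle = FALSE)
    fwd <- ct_forward(model$params, config, batch, train = FALSE)
    beta[fits] <- survival_head(model$params, fwd$P[fwd$task_rows, , drop = FALSE])
  }
  if (any(!fits)) {
    for (i in which(!fits)) {
      b <- vapply(seq_len(n_subsamples), function(s) {
        row <- sample_and_pad(records[[i]], L, vocab, shuffle = TRUE, seed = 7000L + s)
        batch1 <- list(token_ids = matrix(row$token_ids, 1L),
                       values = matrix(row$values, 1L),
                       pad = matrix(row$pad, 1L))
        fwd <- ct_forward(model$params, config, batch1, train = FALSE)
        survival_head(model$params, fwd$P[fwd$task_rows, , drop = FALSE])
      }, numeric(1))
      beta[i] <- mean(b)
    }
  }
  beta
}

#' Extract last-layer output embeddings for a cohort
#'
#' Returns, per patient, the final-encoder-layer embeddings of the TASK
#' position and of every observed (non-PAD) feature position — the
#' representation on which the cosine-similarity explainability operates.
#'
#' @inheritParams predict_scores
#' @return list per patient: `task` (d_k vector), `features` (matrix with
#'   one named row per observed feature).
#' @export
embedding_set <- function(model, cohort, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(cohort$id)
  records <- as_records(cohort)[idx]
  config <- model$config; vocab <- model$vocab; L <- config$max_len
  batch <- encode_batch(records, L, vocab, shuffle = FALSE)
  fwd <- ct_forward(model$params, config, batch, train = FALSE)
  id2name <- stats::setNames(names(vocab$feature_ids), vocab$feature_ids)
  lapply(seq_along(records), function(b) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    tok <- batch$token_ids[b, ]
    keep <- which(!batch$pad[b, ] & tok != vocab$task_id)
    Pfeat <- fwd$P[rows[keep], , drop = FALSE]
    rownames(Pfeat) <- id2name[as.character(tok[keep])]
    list(task = fwd$P[rows[1L], ], features = Pfeat)
  })
}

#' Stratify patients by training-score quantile cutoffs
#'
#' Cutoffs are the 25/50/75 percentiles (or the median for `n_groups = 2`)
#' of the training-split scores; evaluation patients are labeled by interval.
#' Q1 is the lowest-score group (predicted short-term survivors).
#'
#' @param beta_train training-split scores defining the cutoffs.
#' @param beta_eval scores to label (defaults to `beta_train`).
#' @param n_groups 4 for quartiles, 2 for a median high/low split.
#' @return factor of labels `Q1..Qn`.
#' @export
stratify_quartiles <- function(beta_train, beta_eval = beta_train, n_groups = 4L) {
  if (!length(beta_train)) stopf("no training scores given")
  probs <- seq_len(n_groups - 1L) / n_groups
  cuts <- unique(stats::quantile(beta_train, probs, type = 7, names = FALSE))
  if (!length(cuts) || length(unique(beta_train)) == 1L) {
    warnf("degenerate scores: all patients fall in a single group")
    return(factor(rep("Q1", length(beta_eval)), levels = paste0("Q", seq_len(n_groups))))
  }
  lab <- findInterval(beta_eval, cuts, left.open = TRUE) + 1L
  factor(paste0("Q", lab), levels = paste0("Q", seq_len(n_groups)))
}
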