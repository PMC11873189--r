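#' Simulate a clinicogenomic cohort with known ground truth
#'
#' Generates the kind of tabular data the model is designed for: blocks of
#' correlated continuous biomarkers, sparse binary mutation features, a known
#' log-hazard with main effects, optional pairwise interactions and
#' any-mutated group effects, right-censored survival times drawn by inverse
#' transform under proportional hazards, independent exponential censoring
#' calibrated to a target censoring fraction, and missing-at-random cells.
#'
#' The linear predictor `eta` is on the log-hazard scale: positive
#' coefficients shorten survival. `-eta` is therefore the oracle survival
#' score against which model concordance can be compared.
#'
#' @param n number of patients.
#' @param blocks list of blocks, each `list(size =, rho =)` with `rho` in
#'   \[0, 1) the within-block equicorrelation. Block k's features are named
#'   `bk_f1, bk_f2, ...` and are standard normal marginally.
#' @param n_mut number of sparse binary mutation features (`mut1, ...`).
#' @param mut_prev per-mutation prevalence, recycled over mutations.
#' @param coef named numeric vector of log-hazard main effects (names must be
#'   feature names).
#' @param interactions optional list of `list(f1 =, f2 =, coef =)` pairwise
#'   product terms added to the log-hazard.
#' @param group_effects optional list of `list(members = <mutation names>,
#'   coef =)`: an any-mutated indicator over `members` enters the log-hazard.
#' @param baseline `"exponential"` or `"weibull"` baseline event distribution.
#' @param base_rate baseline rate parameter (events per month).
#' @param weibull_shape shape for the Weibull baseline.
#' @param censor_frac target fraction of censored patients in \[0, 1).
#' @param miss_frac per-cell missing-at-random probability in \[0, 1).
#' @param seed RNG seed.
#' @return list with `cohort` (a `ct_cohort`) and `truth` (coefficients,
#'   block membership, per-patient true linear predictor `eta`, censoring
#'   rate used, and the complete pre-missingness feature matrix).
#' @export
simulate_cohort <- function(n,
                            blocks = list(list(size = 4, rho = 0.0)),
                            n_mut = 0, mut_prev = 0.2,
                            coef = NULL, interactions = NULL,
                            group_effects = NULL,
                            baseline = c("exponential", "weibull"),
                            base_rate = 0.05, weibull_shape = 1.5,
                            censor_frac = 0.3, miss_frac = 0,
                            seed = 1L) {
  baseline <- match.arg(baseline)
  stopifnot(n >= 1, censor_frac >= 0, censor_frac < 1,
            miss_frac >= 0, miss_frac < 1)
  if (n_mut > 0) {
    prev <- rep_len(mut_prev, n_mut)
    if (any(prev <= 0 | prev >= 1)) stopf("mutation prevalences must lie in (0, 1)")
  }
  for (b in blocks) if (b$rho < 0 || b$rho >= 1) stopf("block rho must lie in [0, 1)")

  with_seed(seed, {
    cols <- list(); block_of <- character(0)
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      z0 <- stats::rnorm(n)
      x <- sapply(seq_len(b$size), function(j)
        sqrt(b$rho) * z0 + sqrt(1 - b$rho) * stats::rnorm(n))
      colnames(x) <- sprintf("b%d_f%d", k, seq_len(b$size))
      cols[[length(cols) + 1L]] <- x
      block_of <- c(block_of, stats::setNames(rep(sprintf("b%d", k), b$size), colnames(x)))
    }
    if (n_mut > 0) {
      m <- sapply(seq_len(n_mut), function(j) stats::rbinom(n, 1L, prev[j]))
      colnames(m) <- sprintf("mut%d", seq_len(n_mut))
      cols[[length(cols) + 1L]] <- m
      block_of <- c(block_of, stats::setNames(rep("mut", n_mut), colnames(m)))
    }
    X <- do.call(cbind, cols)

    eta <- rep(0, n)
    if (!is.null(coef)) {
      miss <- setdiff(names(coef), colnames(X))
      if (length(miss)) stopf("coef names not among features: %s", paste(miss, collapse = ", "))
      eta <- eta + as.vector(X[, names(coef), drop = FALSE] %*% coef)
    }
    if (!is.null(interactions))
      for (it in interactions) eta <- eta + it$coef * X[, it$f1] * X[, it$f2]
    if (!is.null(group_effects))
      for (ge in group_effects)
        eta <- eta + ge$coef * as.numeric(rowSums(X[, ge$members, drop = FALSE]) > 0)

    # inverse-transform sampling under proportional hazards
    u <- stats::runif(n)
    base_t <- -log(u) / (base_rate * exp(eta))
    t_event <- if (baseline == "exponential") base_t else base_t^(1 / weibull_shape)

    if (censor_frac > 0) {
      # choose the exponential censoring rate whose expected censored fraction,
      # conditional on the drawn event times, matches the target
      f <- function(cr) mean(1 - exp(-cr * t_event)) - censor_frac
      cr <- stats::uniroot(f, lower = 1e-10, upper = 1e6, tol = 1e-10)$root
      t_cens <- stats::rexp(n, rate = cr)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      cr <- 0; time <- t_event; event <- rep(1L, n)
    }

    tab <- X
    if (miss_frac > 0) tab[matrix(stats::runif(length(tab)) < miss_frac,
                                  nrow(tab), ncol(tab))] <- NA_real_

    schema <- ct_schema(id = "patient_id", time = "time", event = "event",
                        features = stats::setNames(
                          ifelse(block_of[colnames(X)] == "mut", "binary", "continuous"),
                          colnames(X)))
    cohort <- structure(list(id = sprintf("P%04d", seq_len(n)), time = time,
                             event = event, tab = tab, schema = schema),
                        class = "ct_cohort")
    list(cohort = cohort,
         truth = list(eta = eta, coef = coef, interactions = interactions,
                      group_effects = group_effects, block_of = block_of,
                      censor_rate = cr, X = X))
  })
}

#' Simulate a cohort with deterministic feature co-occurrence rules
#'
#' A pretraining testbed: each patient carries exactly one feature pair
#' `Ak`/`Bk` (both present, sharing a common value), plus `n_background`
#' always-present noise features. Masking the name of a pair member leaves
#' its partner visible, so the masked-name task is solvable with accuracy 1
#' by construction, far above the uniform-chance rate `1 / n_features`.
#'
#' @param n patients.
#' @param n_pairs number of linked feature pairs.
#' @param n_background number of always-present independent features.
#' @param seed RNG seed.
#' @return list with `cohort` and `truth` (`pair_of`: index of the pair each
#'   patient carries).
#' @export
make_cooccurrence_cohort <- function(n, n_pairs = 4, n_background = 4, seed = 1L) {
  with_seed(seed, {
    pair_of <- sample.int(n_pairs, n, replace = TRUE)
    pa <- sprintf("A%d", seq_len(n_pairs)); pb <- sprintf("B%d", seq_len(n_pairs))
    bg <- sprintf("noise%d", seq_len(n_background))
    feats <- c(rbind(pa, pb), bg)
    tab <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
    v <- stats::rnorm(n)
    for (i in seq_len(n)) {
      tab[i, pa[pair_of[i]]] <- v[i]
      tab[i, pb[pair_of[i]]] <- v[i]
    }
    tab[, bg] <- matrix(stats::rnorm(n * n_background), n)
    time <- stats::rexp(n, 0.05); event <- rep(1L, n)
    schema <- ct_schema("patient_id", "time", "event",
                        stats::setNames(rep("continuous", length(feats)), feats))
    cohort <- structure(list(id = sprintf("P%04d", seq_len(n)), time = time,
                             event = event, tab = tab, schema = schema),
                        class = "ct_cohort")
    list(cohort = cohort, truth = list(pair_of = pair_of, pairs = cbind(A = pa, B = pb)))
  })
}
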