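#' Single-feature in-silico perturbation
#'
#' Replaces one feature's value, for every patient, by each point of a grid
#' drawn from the feature's training distribution (midpoints of its 10
#' deciles by default; the observed unique values when fewer exist), keeping
#' all other features fixed, and rescores each perturbed patient with the
#' trained model. The per-patient spread `delta_beta = max - min` over the
#' grid measures the patient's sensitivity to the feature.
#'
#' @param model a `ct_model`, or a scoring function `cohort -> beta` (useful
#'   for validating the perturbation mechanics against analytic scorers).
#' @param cohort a `ct_cohort` (patients to perturb).
#' @param feature feature name.
#' @param train_values numeric vector of the feature's observed training
#'   values defining the grid (defaults to its values in `cohort`).
#' @param n_grid grid size (default 10 percentile bins).
#' @return list of class `ct_perturbation`: `feature`, `grid`, `beta`
#'   (patients x grid matrix), `baseline` (unperturbed scores),
#'   `delta_beta`, `max_beta`.
#' @export
perturb_single <- function(model, cohort, feature, train_values = NULL,
                           n_grid = 10L) {
  score <- as_scorer(model)
  if (!feature %in% colnames(cohort$tab)) stopf("unknown feature '%s'", feature)
  if (is.null(train_values)) train_values <- cohort$tab[, feature]
  train_values <- train_values[!is.na(train_values)]
  grid <- perturbation_grid(train_values, n_grid)
  beta <- sapply(grid, function(v) {
    pert <- cohort
    pert$tab[, feature] <- v
    score(pert)
  })
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1L)
  baseline <- score(cohort)
  structure(list(feature = feature, grid = grid, beta = beta,
                 baseline = baseline,
                 delta_beta = apply(beta, 1L, max) - apply(beta, 1L, min),
                 max_beta = apply(beta, 1L, max)),
            class = "ct_perturbation")
}

# decile-midpoint grid (or the unique observed values when too few)
perturbation_grid <- function(values, n_grid = 10L) {
  u <- sort(unique(values))
  if (length(u) <= n_grid) return(u)
  as.numeric(stats::quantile(values, probs = (seq_len(n_grid) - 0.5) / n_grid,
                             type = 7, names = FALSE))
}

#' Pairwise in-silico perturbation
#'
#' Jointly perturbs two features: per repeat, each patient receives a pair of
#' values drawn from the features' empirical training distributions, all
#' other features held fixed, and is rescored. Repeated `n_repeats` times
#' (default 50). When `f == g` the pair degenerates to repeated
#' single-feature sampling.
#'
#' @param model a `ct_model`.
#' @param cohort a `ct_cohort`.
#' @param features character vector of two feature names (or one repeated).
#' @param train_tab training feature matrix supplying the empirical value
#'   distributions (defaults to `cohort$tab`).
#' @param n_repeats number of joint draws per patient (default 50).
#' @param seed RNG seed.
#' @return `ct_perturbation` with `beta` (patients x repeats), `delta_beta`,
#'   `max_beta` (the per-patient maximum survival score `M_p(f, g)`).
#' @export
perturb_pair <- function(model, cohort, features, train_tab = NULL,
                         n_repeats = 50L, seed = 1L) {
  score <- as_scorer(model)
  stopifnot(length(features) %in% c(1L, 2L))
  f <- features[1L]; g <- features[min(2L, length(features))]
  if (is.null(train_tab)) train_tab <- cohort$tab
  vf <- train_tab[, f]; vf <- vf[!is.na(vf)]
  vg <- train_tab[, g]; vg <- vg[!is.na(vg)]
  n <- length(cohort$id)
  beta <- with_seed(seed, {
    sapply(seq_len(n_repeats), function(r) {
      pert <- cohort
      draw_f <- sample(vf, n, replace = TRUE)
      pert$tab[, f] <- draw_f
      if (g != f) pert$tab[, g] <- sample(vg, n, replace = TRUE)
      score(pert)
    })
  })
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1L)
  baseline <- score(cohort)
  structure(list(feature = c(f, g), grid = NULL, beta = beta,
                 baseline = baseline,
                 delta_beta = apply(beta, 1L, max) - apply(beta, 1L, min),
                 max_beta = apply(beta, 1L, max)),
            class = "ct_perturbation")
}

#' Interaction significance of perturbation responses
#'
#' Compares the distribution of per-patient maximum perturbed survival
#' scores, for each single feature and feature pair, against the unperturbed
#' score distribution with a two-sided Mann-Whitney rank-sum test, and
#' summarizes each pair by
#' `Diff = max(-log10 p(f), -log10 p(g)) - (-log10 p(f, g))`.
#' Negative `Diff` means the joint perturbation is more significant than
#' either marginal one — an interaction; `Diff = 0` when the pair is exactly
#' as significant as its best marginal.
#'
#' @param singles named list of `ct_perturbation`s from [perturb_single()]
#'   (names = features).
#' @param pairs named list of `ct_perturbation`s from [perturb_pair()]
#'   (names like `"f:g"`).
#' @param baseline numeric vector of unperturbed scores of the same
#'   population.
#' @param log_base base of the log transform (default 10).
#' @return data.frame f / g / p_f / p_g / p_fg / diff.
#' @export
interaction_significance <- function(singles, pairs, baseline, log_base = 10) {
  if (length(baseline) < 8L) warnf("population of %d patients: rank-sum tests underpowered", length(baseline))
  pval <- function(x) stats::wilcox.test(x, baseline, exact = FALSE)$p.value
  p_single <- vapply(singles, function(p) pval(p$max_beta), numeric(1))
  rows <- lapply(names(pairs), function(nm) {
    fg <- strsplit(nm, ":", fixed = TRUE)[[1]]
    p_fg <- pval(pairs[[nm]]$max_beta)
    pf <- p_single[[fg[1]]]; pg <- p_single[[fg[2]]]
    data.frame(f = fg[1], g = fg[2], p_f = pf, p_g = pg, p_fg = p_fg,
               diff = diff_score(pf, pg, p_fg, log_base))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Interaction Diff score
#'
#' `Diff = max(-log p(f), -log p(g)) - (-log p(f, g))`, log base 10 by
#' default. Negative values flag interactions whose joint perturbation
#' effect exceeds both marginal effects.
#' @param p_f,p_g,p_fg p-values for the two marginal perturbations and the
#'   joint one.
#' @param log_base log base.
#' @export
diff_score <- function(p_f, p_g, p_fg, log_base = 10) {
  nl <- function(p) -log(p, base = log_base)
  max(nl(p_f), nl(p_g)) - nl(p_fg)
}

#' Split a population into perturbation-variant and -invariant halves
#'
#' Median split of the per-patient `delta_beta` within a restriction filter
#' (by default the predicted short and low-mid survivors, quartiles Q1 and
#' Q2): patients above the median are the variant population, the rest the
#' invariant one; sizes differ by at most 1. When training quartile cutoffs
#' are supplied, variant patients whose maximum perturbed score crosses the
#' Q1 cutoff upward (an in-silico transition to improved predicted survival)
#' are flagged.
#'
#' @param delta_beta per-patient perturbation spread (see
#'   [perturb_single()]).
#' @param filter_idx indices of the restriction population (default: all).
#' @param max_beta optional per-patient maximum perturbed score.
#' @param baseline optional unperturbed scores.
#' @param q1_cutoff optional training Q1 (25th percentile) score cutoff.
#' @return list of class `ct_popsplit`: `variant`, `invariant` (indices into
#'   the original population), `median`, `crossers` (subset of `variant`
#'   whose `max_beta` exceeds `q1_cutoff` while `baseline` did not).
#' @export
split_variant_invariant <- function(delta_beta, filter_idx = NULL,
                                    max_beta = NULL, baseline = NULL,
                                    q1_cutoff = NULL) {
  if (is.null(filter_idx)) filter_idx <- seq_along(delta_beta)
  d <- delta_beta[filter_idx]
  n <- length(d)
  med <- stats::median(d)
  if (length(unique(d)) == 1L)
    warnf("all delta_beta equal: variant/invariant split by stable patient order")
  r <- rank(d, ties.method = "first")
  variant <- filter_idx[r > n / 2]
  invariant <- filter_idx[r <= n / 2]
  crossers <- integer(0)
  if (!is.null(q1_cutoff) && !is.null(max_beta) && !is.null(baseline))
    crossers <- intersect(variant,
                          which(max_beta > q1_cutoff & baseline <= q1_cutoff))
  structure(list(variant = variant, invariant = invariant, median = med,
                 crossers = crossers),
            class = "ct_popsplit")
}

#' Feature contrasts between variant and invariant populations
#'
#' Per input feature, a two-sided t test between the variant and invariant
#' patients' values with Bonferroni correction over the tested features.
#' Binary features are summarized as proportions. Constant features are
#' skipped.
#'
#' @param split a [split_variant_invariant()] result.
#' @param cohort the `ct_cohort` the split indexes into.
#' @return data.frame feature / mean_variant / mean_invariant / p /
#'   p_bonferroni / stars.
#' @export
compare_populations <- function(split, cohort) {
  rows <- list()
  for (f in colnames(cohort$tab)) {
    xv <- cohort$tab[split$variant, f]; xv <- xv[!is.na(xv)]
    xi <- cohort$tab[split$invariant, f]; xi <- xi[!is.na(xi)]
    if (length(xv) < 2L || length(xi) < 2L) next
    if (stats::var(c(xv, xi)) == 0) next
    p <- tryCatch(stats::t.test(xv, xi)$p.value, error = function(e) NA_real_)
    rows[[f]] <- data.frame(feature = f, mean_variant = mean(xv),
                            mean_invariant = mean(xi), p = p)
  }
  if (!length(rows)) return(data.frame())
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(res$p * nrow(res), 1)
  res$stars <- cut(res$p_bonferroni, c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                   labels = c("****", "***", "**", "*", "ns"))
  rownames(res) <- NULL
  res
}

# accept either a fitted model or a plain scoring function
as_scorer <- function(model) {
  if (is.function(model)) model else function(cohort) predict_scores(model, cohort)
}
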