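#' Permutation feature importance
#'
#' For each feature, the observed values are shuffled across the patients
#' that carry the feature (missingness pattern preserved), the cohort is
#' rescored, and the drop in concordance `C_baseline - C_permuted` is
#' recorded. Features with no influence on the model concentrate at 0.
#'
#' @param model a `ct_model`, or a scoring function `cohort -> beta`.
#' @param cohort a `ct_cohort` with outcomes.
#' @param idx patient indices to evaluate on (e.g. a test split); default all.
#' @param n_repeats permutation draws per feature (default 10).
#' @param seed RNG seed.
#' @return data.frame feature / repeat / importance, plus attribute
#'   `baseline` (unpermuted concordance).
#' @export
permutation_importance <- function(model, cohort, idx = NULL, n_repeats = 10,
                                   seed = 1L) {
  score <- as_scorer(model)
  if (is.null(idx)) idx <- seq_along(cohort$id)
  sub <- cohort_subset(cohort, idx)
  base_c <- c_index(score(sub), sub$time, sub$event)
  out <- list()
  with_seed(seed, {
    for (f in colnames(sub$tab)) {
      obs <- which(!is.na(sub$tab[, f]))
      if (length(obs) == 0L) {
        out[[f]] <- data.frame(feature = f, repetition = seq_len(n_repeats),
                               importance = 0)
        next
      }
      if (length(obs) < 2L) {
        warnf("feature '%s' observed in < 2 patients: skipped", f)
        next
      }
      imp <- vapply(seq_len(n_repeats), function(r) {
        perm <- sub
        perm$tab[obs, f] <- sub$tab[obs[sample.int(length(obs))], f]
        base_c - c_index(score(perm), perm$time, perm$event)
      }, numeric(1))
      out[[f]] <- data.frame(feature = f, repetition = seq_len(n_repeats),
                             importance = imp)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "baseline") <- base_c
  res
}

# subset a cohort by patient index
cohort_subset <- function(cohort, idx) {
  structure(list(id = cohort$id[idx], time = cohort$time[idx],
                 event = cohort$event[idx],
                 tab = cohort$tab[idx, , drop = FALSE], schema = cohort$schema),
            class = "ct_cohort")
}

#' Cosine similarity between two embedding vectors
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return cosine in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stopf("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Population-mean feature-interaction matrix from output embeddings
#'
#' "Post-attention": for each patient, the pairwise cosine similarities among
#' the last-layer output embeddings of all observed features and of the
#' outcome (TASK) position; the population matrix averages each pair over the
#' patients in which both members are observed. The `"(outcome)"` row/column
#' holds each feature's cosine to the outcome embedding, which ranks features
#' by their contribution to the prediction.
#'
#' @param model a `ct_model`.
#' @param cohort a `ct_cohort`.
#' @param idx optional patient indices (a population filter).
#' @return list of class `ct_interactions`: `S` symmetric mean-cosine matrix
#'   (NA where a pair is never co-observed), `coverage` co-observation counts.
#' @export
interaction_matrix <- function(model, cohort, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(cohort$id)
  emb <- embedding_set(model, cohort, idx)
  feats <- c(colnames(cohort$tab), "(outcome)")
  Fn <- length(feats)
  Ssum <- matrix(0, Fn, Fn, dimnames = list(feats, feats))
  cnt <- matrix(0L, Fn, Fn, dimnames = list(feats, feats))
  for (e in emb) {
    M <- rbind(e$features, `(outcome)` = e$task)
    nrm <- sqrt(rowSums(M^2))
    Cs <- tcrossprod(M / nrm)
    pos <- match(rownames(M), feats)
    Ssum[pos, pos] <- Ssum[pos, pos] + Cs
    cnt[pos, pos] <- cnt[pos, pos] + 1L
  }
  S <- Ssum / cnt
  S[cnt == 0L] <- NA_real_
  structure(list(S = S, coverage = cnt, n_patients = length(emb)),
            class = "ct_interactions")
}

#' Cluster features into functional groups
#'
#' Clusters the feature rows of the population interaction matrix (distance
#' `1 - cosine`; never-co-observed pairs imputed with cosine 1 before
#' clustering). Agglomerative clustering with average linkage is the default;
#' k-means on the similarity rows is available. With `n_groups = NULL` the
#' group count is chosen by the mean silhouette over 2..`max_groups`.
#'
#' @param interactions a [interaction_matrix()] result (or a plain symmetric
#'   similarity matrix).
#' @param n_groups number of groups, or `NULL` for silhouette-based choice.
#' @param method `"agglomerative"` or `"kmeans"`.
#' @param max_groups upper bound scanned in auto mode.
#' @param seed RNG seed (k-means restarts).
#' @return list of `ct_functional_group`s: `id` (e.g. `"C1"`), `members`,
#'   `mean_within_cosine`; attribute `assignment` (named integer vector).
#' @export
cluster_functional_groups <- function(interactions, n_groups = NULL,
                                      method = c("agglomerative", "kmeans"),
                                      max_groups = 10L, seed = 1L) {
  method <- match.arg(method)
  S <- if (inherits(interactions, "ct_interactions")) interactions$S else interactions
  keep <- setdiff(rownames(S), "(outcome)")
  S <- S[keep, keep, drop = FALSE]
  S[is.na(S)] <- 1  # missing pairs encoded with 1 before clustering
  Fn <- nrow(S)
  if (!is.null(n_groups) && n_groups > Fn) stopf("more groups requested (%d) than features (%d)", n_groups, Fn)
  D <- stats::as.dist(pmax(1 - S, 0))
  assign_k <- function(k) {
    if (k >= Fn) return(stats::setNames(seq_len(Fn), rownames(S)))
    if (method == "agglomerative") {
      stats::cutree(stats::hclust(D, method = "average"), k = k)
    } else {
      with_seed(seed, stats::kmeans(S, centers = k, nstart = 10L)$cluster)
    }
  }
  if (is.null(n_groups)) {
    ks <- seq(2L, min(max_groups, Fn - 1L))
    sil <- vapply(ks, function(k) {
      cl <- assign_k(k)
      mean(cluster::silhouette(cl, D)[, "sil_width"])
    }, numeric(1))
    n_groups <- ks[which.max(sil)]
  }
  cl <- assign_k(n_groups)
  groups <- lapply(sort(unique(cl)), function(k) {
    members <- names(cl)[cl == k]
    mwc <- if (length(members) > 1L) {
      sub <- S[members, members]
      mean(sub[upper.tri(sub)])
    } else 1
    structure(list(id = paste0("C", k), members = members,
                   mean_within_cosine = mwc),
              class = "ct_functional_group")
  })
  attr(groups, "assignment") <- cl
  groups
}

#' Rank functional groups across subpopulations
#'
#' For each group and subpopulation, the mean within-group cosine and the
#' mean group-to-outcome cosine are computed from the subpopulation's own
#' interaction matrix; groups are ranked per subpopulation by within-group
#' cosine. Groups ranked high everywhere are "core"; groups enriched in
#' specific subpopulations are "target" groups.
#'
#' @param groups result of [cluster_functional_groups()].
#' @param model a `ct_model`.
#' @param cohort a `ct_cohort`.
#' @param subpop factor/vector of subpopulation labels, one per patient
#'   (e.g. survival-score quartiles from [stratify_quartiles()]).
#' @return data.frame group / subpopulation / mean_within_cosine /
#'   mean_outcome_cosine / rank (1 = highest within-cosine in that
#'   subpopulation).
#' @export
rank_functional_groups <- function(groups, model, cohort, subpop) {
  stopifnot(length(subpop) == length(cohort$id))
  out <- list()
  for (lev in levels(factor(subpop))) {
    idx <- which(subpop == lev)
    S <- interaction_matrix(model, cohort, idx)$S
    stats_g <- lapply(groups, function(g) {
      m <- g$members
      within <- if (length(m) > 1L) {
        sub <- S[m, m]; mean(sub[upper.tri(sub)], na.rm = TRUE)
      } else 1
      outc <- mean(S[m, "(outcome)"], na.rm = TRUE)
      data.frame(group = g$id, subpopulation = lev,
                 mean_within_cosine = within, mean_outcome_cosine = outc)
    })
    df <- do.call(rbind, stats_g)
    df$rank <- rank(-df$mean_within_cosine, ties.method = "min")
    out[[lev]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binarize a functional group over a mutation table
#'
#' A patient's group indicator is 1 iff at least one member gene is mutated:
#' `zeta[i] = 1 if sum_g x[i, g] > 0`.
#'
#' @param group a `ct_functional_group` (or character vector of members).
#' @param mutation_tab numeric matrix/data.frame of binary mutation columns
#'   (NA treated as 0 = not mutated).
#' @return integer vector in \{0, 1\}, one per patient.
#' @export
binarize_group <- function(group, mutation_tab) {
  members <- if (inherits(group, "ct_functional_group")) group$members else group
  miss <- setdiff(members, colnames(mutation_tab))
  if (length(miss)) stopf("group members absent from mutation table: %s", paste(miss, collapse = ", "))
  sub <- as.matrix(mutation_tab[, members, drop = FALSE])
  if (!all(sub %in% c(0, 1, NA))) stopf("group members must be binary mutation columns")
  sub[is.na(sub)] <- 0
  as.integer(rowSums(sub) > 0)
}

#' Univariate Cox validation of binarized functional groups
#'
#' Fits one univariate Cox proportional-hazards model per group indicator,
#' keeps groups with Wald p < 0.05 (Benjamini-Hochberg adjusted values are
#' reported alongside for transparency), and ranks them by hazard ratio.
#' Both protective (HR < 1) and deleterious (HR > 1) groups are reported.
#'
#' @param indicators matrix/data.frame of binary group indicators (one column
#'   per group).
#' @param time,event survival outcome.
#' @param p_cutoff significance filter on the raw Wald p (default 0.05).
#' @return data.frame group / coef / hr / ci_lower / ci_upper / p / p_bh /
#'   significant, ordered by hazard ratio.
#' @export
validate_groups_cox <- function(indicators, time, event, p_cutoff = 0.05) {
  indicators <- as.data.frame(indicators)
  rows <- list()
  for (g in names(indicators)) {
    x <- indicators[[g]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      warnf("group '%s' is constant: skipped", g)
      next
    }
    fit <- tryCatch(survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
                    error = function(e) NULL, warning = function(w) {
                      # convergence warnings (e.g. separation) -> skip group
                      NULL
                    })
    if (is.null(fit)) { warnf("group '%s': Cox fit failed, skipped", g); next }
    sm <- summary(fit)
    rows[[g]] <- data.frame(group = g, coef = unname(stats::coef(fit)),
                            hr = unname(sm$conf.int[1, "exp(coef)"]),
                            ci_lower = unname(sm$conf.int[1, "lower .95"]),
                            ci_upper = unname(sm$conf.int[1, "upper .95"]),
                            p = unname(sm$coefficients[1, "Pr(>|z|)"]))
  }
  if (!length(rows)) return(data.frame())
  res <- do.call(rbind, rows)
  res$p_bh <- stats::p.adjust(res$p, "BH")
  res$significant <- res$p < p_cutoff
  res <- res[order(res$hr), ]
  rownames(res) <- NULL
  res
}

#' Distill the model into a multivariate Cox model on top functional groups
#'
#' Fits a multivariate Cox proportional-hazards model on the top-k binarized
#' functional groups over each training split, evaluates test-split
#' concordance, and stratifies test patients by the median training risk
#' score. A control fit on `k` random same-size feature groups quantifies how
#' much of the performance is due to the model-guided selection.
#'
#' @param indicators binary indicator matrix for the selected top groups
#'   (columns = groups).
#' @param time,event survival outcome.
#' @param splits list from [make_splits()].
#' @param control_tab optional full binary feature table from which random
#'   control groups are drawn (column count per group mirrors `group_sizes`).
#' @param group_sizes integer vector of member counts of the real groups
#'   (required with `control_tab`).
#' @param seed RNG seed for the random control.
#' @return list: `summary` (pooled multivariate coefficients over splits),
#'   `test_cindex` per split, `control_cindex` per split (or NULL),
#'   `stratification` data.frame (split, patient index, risk group).
#' @export
simplify_to_cox <- function(indicators, time, event, splits,
                            control_tab = NULL, group_sizes = NULL, seed = 1L) {
  indicators <- as.matrix(indicators)
  if (ncol(indicators) == 0L) stopf("no group indicators supplied")
  fit_eval <- function(X) {
    vapply(seq_along(splits), function(s) {
      sp <- splits[[s]]
      df <- as.data.frame(X)
      fit <- survival::coxph(survival::Surv(time[sp$train], event[sp$train]) ~ .,
                             data = df[sp$train, , drop = FALSE], ties = "efron")
      risk <- as.vector(as.matrix(df[sp$test, , drop = FALSE]) %*% stats::coef(fit))
      # higher risk = shorter survival, so score = -risk
      c_index(-risk, time[sp$test], event[sp$test])
    }, numeric(1))
  }
  test_c <- fit_eval(indicators)
  control_c <- NULL
  if (!is.null(control_tab)) {
    if (is.null(group_sizes)) group_sizes <- rep(1L, ncol(indicators))
    ctrl <- with_seed(seed, sapply(group_sizes, function(k) {
      members <- sample(colnames(control_tab), min(k, ncol(control_tab)))
      binarize_group(members, control_tab)
    }))
    colnames(ctrl) <- paste0("R", seq_along(group_sizes))
    control_c <- fit_eval(ctrl)
  }
  # pooled fit + median-risk stratification per split
  strat <- list(); coefs <- list()
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    df <- as.data.frame(indicators)
    fit <- survival::coxph(survival::Surv(time[sp$train], event[sp$train]) ~ .,
                           data = df[sp$train, , drop = FALSE], ties = "efron")
    coefs[[s]] <- stats::coef(fit)
    risk_tr <- as.vector(as.matrix(df[sp$train, , drop = FALSE]) %*% stats::coef(fit))
    risk_te <- as.vector(as.matrix(df[sp$test, , drop = FALSE]) %*% stats::coef(fit))
    med <- stats::median(risk_tr)
    strat[[s]] <- data.frame(split = s, index = sp$test,
                             risk_group = ifelse(risk_te > med, "high", "low"))
  }
  list(summary = do.call(rbind, coefs), test_cindex = test_c,
       control_cindex = control_c, stratification = do.call(rbind, strat))
}
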