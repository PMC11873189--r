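test_that("cosine similarity matches explicit arithmetic and rejects zero vectors", {
  v <- c(1, -2, 3)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, -v), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / (sqrt(14) * sqrt(77)))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("permutation importance is exactly zero for an all-missing feature", {
  f <- small_trained_fit()
  co <- f$sim$cohort
  co$tab <- cbind(co$tab, ghost = NA_real_)
  co$schema$features <- c(co$schema$features, ghost = "continuous")
  # score with the fitted model, which simply never sees the ghost feature
  scorer <- function(ch) {
    ch$tab <- ch$tab[, names(f$model$vocab$feature_ids), drop = FALSE]
    predict_scores(f$model, ch)
  }
  imp <- permutation_importance(scorer, co, n_repeats = 3, seed = 1)
  expect_true(all(imp$importance[imp$feature == "ghost"] == 0))
})

test_that("permutation importance ranks a planted signal above noise (toy scorer)", {
  sim <- simulate_cohort(150, blocks = list(list(size = 5, rho = 0)),
                         coef = c(b1_f1 = 1.2), censor_frac = 0.2, seed = 10)
  co <- sim$cohort
  scorer <- function(ch) -ch$tab[, "b1_f1"]  # the true (negated) hazard driver
  imp <- permutation_importance(scorer, co, n_repeats = 5, seed = 2)
  means <- tapply(imp$importance, imp$feature, mean)
  expect_equal(names(which.max(means)), "b1_f1")
  expect_lt(max(abs(means[setdiff(names(means), "b1_f1")])), 0.02)
})

test_that("interaction matrix of a single patient equals that patient's cosines", {
  f <- small_trained_fit()
  co <- f$sim$cohort
  im1 <- interaction_matrix(f$model, co, idx = 1)
  emb <- embedding_set(f$model, co, idx = 1)[[1]]
  for (a in rownames(emb$features)) for (b in rownames(emb$features)) {
    expect_equal(im1$S[a, b],
                 cosine_similarity(emb$features[a, ], emb$features[b, ]),
                 tolerance = 1e-12)
  }
  expect_equal(im1$S["(outcome)", rownames(emb$features)[1]],
               cosine_similarity(emb$task, emb$features[1, ]), tolerance = 1e-12)
})

test_that("interaction matrix is symmetric with unit diagonal and tracks coverage", {
  f <- small_trained_fit()
  co <- f$sim$cohort
  co$tab[1:40, "b1_f3"] <- NA  # induce partial coverage
  im <- interaction_matrix(f$model, co, idx = 1:60)
  S <- im$S
  expect_equal(S, t(S), tolerance = 1e-12)
  obs <- colnames(co$tab)
  expect_equal(unname(diag(S)[obs]), rep(1, length(obs)), tolerance = 1e-9)
  expect_equal(unname(im$coverage["b1_f3", "b1_f1"]), 20L)
  # a pair never co-observed is flagged missing
  co2 <- co
  co2$tab[, "b1_f3"] <- NA; co2$tab[31:60, "b1_f4"] <- NA
  co2$tab[1:30, "b1_f3"] <- 1
  im2 <- interaction_matrix(f$model, co2, idx = 31:60)
  expect_true(is.na(im2$S["b1_f3", "b1_f1"]))
})

test_that("clustering recovers planted block structure and honors boundaries", {
  # block-diagonal similarity with two perfect blocks
  S <- diag(6) * 0 + 0.05
  S[1:3, 1:3] <- 0.95; S[4:6, 4:6] <- 0.95; diag(S) <- 1
  rownames(S) <- colnames(S) <- sprintf("f%d", 1:6)
  for (m in c("agglomerative", "kmeans")) {
    g <- cluster_functional_groups(S, n_groups = 2, method = m, seed = 1)
    members <- lapply(g, `[[`, "members")
    expect_setequal(vapply(members, function(x) paste(sort(x), collapse = ","),
                           character(1)),
                    c("f1,f2,f3", "f4,f5,f6"))
  }
  # auto mode picks 2 groups by silhouette
  g_auto <- cluster_functional_groups(S, n_groups = NULL, seed = 1)
  expect_length(g_auto, 2)
  # n_groups = n features -> singletons; larger is fatal
  g1 <- cluster_functional_groups(S, n_groups = 6)
  expect_true(all(lengths(lapply(g1, `[[`, "members")) == 1))
  expect_error(cluster_functional_groups(S, n_groups = 7), "more groups")
  # determinism given seed
  expect_identical(cluster_functional_groups(S, 2, "kmeans", seed = 3),
                   cluster_functional_groups(S, 2, "kmeans", seed = 3))
})

test_that("group ranking scores a perfect group first and orthogonal groups near zero", {
  f <- small_trained_fit()
  co <- f$sim$cohort
  im <- interaction_matrix(f$model, co)
  groups <- cluster_functional_groups(im, n_groups = 3, seed = 1)
  quart <- stratify_quartiles(predict_scores(f$model, co))
  rk <- rank_functional_groups(groups, f$model, co, quart)
  expect_setequal(unique(rk$group), vapply(groups, `[[`, character(1), "id"))
  expect_true(all(rk$rank >= 1 & rk$rank <= length(groups)))
  # every subpopulation has a top-ranked group (ties share the min rank)
  for (lev in unique(rk$subpopulation))
    expect_gte(sum(rk$rank[rk$subpopulation == lev] == 1), 1)
})

test_that("group binarization equals a row-wise any() scan", {
  set.seed(12)
  M <- matrix(rbinom(5 * 3, 1, 0.4), 5, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  z <- binarize_group(c("g1", "g3"), M)
  expect_equal(z, as.integer(apply(M[, c("g1", "g3")], 1, function(r) any(r > 0))))
  expect_equal(binarize_group("g2", matrix(0, 4, 1, dimnames = list(NULL, "g2"))),
               rep(0L, 4))
  expect_error(binarize_group("g1", matrix(2, 2, 1, dimnames = list(NULL, "g1"))),
               "binary")
})

test_that("univariate Cox screening controls type-I error and recovers planted effects", {
  set.seed(13)
  covered <- 0L; reps <- 60
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(200, blocks = list(list(size = 2, rho = 0)),
                           n_mut = 1, mut_prev = 0.4, censor_frac = 0.2,
                           seed = 500 + r)
    res <- validate_groups_cox(data.frame(g = sim$cohort$tab[, "mut1"]),
                               sim$cohort$time, sim$cohort$event)
    covered <- covered + (res$ci_lower <= 1 && res$ci_upper >= 1)
  }
  expect_gte(covered / reps, 0.88)  # null indicator: CI covers ~95% nominally
  # planted protective group effect, log-HR -0.7
  hrs <- vapply(1:20, function(r) {
    sim <- simulate_cohort(500, blocks = list(list(size = 2, rho = 0)),
                           n_mut = 1, mut_prev = 0.4,
                           group_effects = list(list(members = "mut1",
                                                     coef = -0.7)),
                           censor_frac = 0.3, seed = 900 + r)
    validate_groups_cox(data.frame(g = sim$cohort$tab[, "mut1"]),
                        sim$cohort$time, sim$cohort$event)$hr
  }, numeric(1))
  expect_equal(mean(hrs), exp(-0.7), tolerance = 0.15 / exp(-0.7))
  # degenerate all-zero indicator is skipped with a warning
  expect_warning(res0 <- validate_groups_cox(data.frame(z = rep(0, 50)),
                                             rexp(50), rbinom(50, 1, 0.8)),
                 "constant")
  expect_equal(nrow(res0), 0)
})

test_that("Cox distillation beats a random-group control on planted group effects", {
  sim <- simulate_cohort(400, blocks = list(list(size = 2, rho = 0)),
                         n_mut = 12, mut_prev = 0.25,
                         group_effects = list(
                           list(members = c("mut1", "mut2", "mut3"), coef = -0.8),
                           list(members = c("mut4", "mut5"), coef = 0.7)),
                         censor_frac = 0.25, seed = 14)
  co <- sim$cohort
  splits <- make_splits(co, n_splits = 5, seed = 14)
  ind <- cbind(G1 = binarize_group(c("mut1", "mut2", "mut3"), co$tab),
               G2 = binarize_group(c("mut4", "mut5"), co$tab))
  noise_cols <- sprintf("mut%d", 6:12)
  res <- simplify_to_cox(ind, co$time, co$event, splits,
                         control_tab = co$tab[, noise_cols],
                         group_sizes = c(3, 2), seed = 14)
  expect_length(res$test_cindex, 5)
  expect_gt(mean(res$test_cindex), mean(res$control_cindex))
  expect_true(all(res$stratification$risk_group %in% c("high", "low")))
  expect_error(simplify_to_cox(ind[, 0], co$time, co$event, splits), "no group")
})
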