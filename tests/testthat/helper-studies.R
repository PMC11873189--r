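# The validation studies shared by the higher-level tests. Each is computed
# once per test run and memoized; study conditions (sizes, effects, seeds)
# are fixed design choices documented in the methods vignette.

.study_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.study_env[[key]])) .study_env[[key]] <- force(expr)
  .study_env[[key]]
}

# --- signal recovery: 600 patients, 12 features, 4 informative ---
recovery_study <- function() memo("recovery", {
  sim <- simulate_cohort(600, blocks = list(list(size = 12, rho = 0)),
                         coef = c(b1_f1 = 0.5, b1_f2 = 0.5,
                                  b1_f3 = -0.5, b1_f4 = -0.5),
                         censor_frac = 0.3, seed = 11)
  splits <- make_splits(sim$cohort, n_splits = 10, seed = 5)
  fit <- fine_tune(sim$cohort, splits, epochs = 30, batch_size = 64,
                   d_k = 64, n_layers = 2, n_heads = 4, lr = 1e-3, seed = 3)
  list(sim = sim, splits = splits, fit = fit,
       informative = c("b1_f1", "b1_f2", "b1_f3", "b1_f4"))
})

# --- functional groups: three rho=0.8 blocks, gradual learning, pooled S ---
groups_study <- function() memo("groups", {
  coefs <- c(b1_f1 = 0.3, b1_f2 = 0.3, b1_f3 = 0.3, b1_f4 = 0.3,
             b2_f1 = -0.3, b2_f2 = -0.3, b2_f3 = -0.3, b2_f4 = -0.3,
             b3_f1 = 0.25, b3_f2 = 0.25, b3_f3 = 0.25, b3_f4 = 0.25)
  sim <- simulate_cohort(500, blocks = list(list(size = 4, rho = 0.8),
                                            list(size = 4, rho = 0.8),
                                            list(size = 4, rho = 0.8)),
                         coef = coefs, censor_frac = 0.3, miss_frac = 0.25,
                         seed = 305)
  co <- sim$cohort
  cfg <- ct_config(ct_vocab(co)$size, compute_max_length(co, 95), d_k = 32,
                   n_layers = 2, n_heads = 4, ff_dim = 128)
  ck <- pretrain(co, config = cfg, iters = 3000, batch_size = 32, lr = 1e-3,
                 seed = 5)
  splits <- make_splits(co, n_splits = 4, seed = 5)
  fit <- fine_tune(co, splits, checkpoint = ck, epochs = 12, batch_size = 64,
                   lr = 1e-3, seed = 5)
  # pool: average the test-split interaction matrices over the split models
  S <- Reduce(`+`, lapply(seq_along(splits), function(s)
    interaction_matrix(fit$models[[s]], co, idx = splits[[s]]$test)$S)) /
    length(splits)
  list(sim = sim, fit = fit, S = S)
})

# --- perturbation discovery: one seed of the carrier-interaction study ---
perturb_discovery_seed <- function(seed) {
  sim <- simulate_cohort(400, blocks = list(list(size = 6, rho = 0)),
                         n_mut = 1, mut_prev = 0.5,
                         coef = c(b1_f1 = 0.3),
                         interactions = list(list(f1 = "b1_f1", f2 = "mut1",
                                                  coef = 1.0)),
                         censor_frac = 0.3, seed = 200 + seed)
  co <- sim$cohort
  splits <- make_splits(co, n_splits = 1, seed = seed)
  fit <- fine_tune(co, splits, epochs = 15, batch_size = 64, d_k = 32,
                   n_layers = 2, n_heads = 4, lr = 1e-3, seed = seed)
  pert <- perturb_single(fit$models[[1]], co, "b1_f1")
  sp <- split_variant_invariant(pert$delta_beta)
  carrier <- co$tab[, "mut1"]
  tb <- table(factor(seq_along(carrier) %in% sp$variant, c(FALSE, TRUE)),
              factor(carrier, c(0, 1)))
  ft <- stats::fisher.test(tb)
  list(or = unname(ft$estimate), p = ft$p.value,
       test_c = utils::tail(fit$curves$c_index, 1))
}

# --- gradual learning: epochs to reach C = 0.60, pretrained vs direct ---
gradual_seed <- function(seed) {
  coefs <- c(b1_f1 = 0.25, b1_f2 = 0.25, b1_f3 = 0.25, b1_f4 = 0.25,
             b2_f1 = -0.2, b2_f2 = -0.2)
  sim <- simulate_cohort(300, blocks = list(list(size = 4, rho = 0.8),
                                            list(size = 4, rho = 0.8),
                                            list(size = 4, rho = 0.8)),
                         coef = coefs, censor_frac = 0.3, seed = 100 + seed)
  co <- sim$cohort
  splits <- make_splits(co, n_splits = 1, seed = seed)
  cfg <- ct_config(ct_vocab(co)$size, compute_max_length(co, 95), d_k = 32,
                   n_layers = 2, n_heads = 4, ff_dim = 128)
  ck <- pretrain(co, config = cfg, iters = 2000, batch_size = 32, lr = 1e-3,
                 seed = seed)
  epochs_to <- function(fit, thr = 0.60) {
    w <- which(fit$curves$c_index >= thr)
    if (length(w)) fit$curves$epoch[w[1]] else Inf
  }
  pre <- fine_tune(co, splits, checkpoint = ck, epochs = 15, batch_size = 32,
                   lr = 3e-4, seed = seed)
  direct <- fine_tune(co, splits, config = cfg, epochs = 15, batch_size = 32,
                      lr = 3e-4, seed = seed)
  c(pretrained = epochs_to(pre), direct = epochs_to(direct))
}
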