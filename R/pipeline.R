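#' Run the end-to-end analysis pipeline
#'
#' Thin orchestration over the package's functions: simulate (or load) a
#' cohort, optionally pretrain, train survival models over random splits,
#' run permutation importance and functional-group discovery, run
#' single-feature perturbations with a variant/invariant split, and write
#' CSV/JSON outputs. A resolved copy of the configuration and a seed
#' manifest are written to the output directory; runs are idempotent given
#' identical configuration and seed.
#'
#' @param config a YAML file path or a named list. Recognized entries:
#'   `stages` (character subset of `"simulate"`, `"pretrain"`, `"train"`,
#'   `"explain"`, `"perturb"`), `seed`, `out_dir`, `cohort_path` +
#'   `schema` (when not simulating), `simulate` (arguments to
#'   [simulate_cohort()]), `model` (d_k, n_layers, n_heads, dropout, sigma),
#'   `train` (n_splits, train_frac, epochs, batch_size, lr),
#'   `pretrain` (iters, batch_size, lr), `explain` (n_groups, n_repeats),
#'   `perturb` (feature, n_grid).
#' @return the output directory path, invisibly; outputs: `cohort.csv`,
#'   `metrics.csv` (split/epoch/c_index), `scores.csv`, `importance.csv`,
#'   `interactions.csv`, `groups.json`, `perturbation.csv`,
#'   `populations.csv`, `config_resolved.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "train", "explain", "perturb")
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stopf("config must name an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(config = config, seed = seed),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  if ("simulate" %in% stages) {
    if (!is.null(config$simulate$coef))
      config$simulate$coef <- unlist(config$simulate$coef)  # YAML lists -> named numeric
    sim <- do.call(simulate_cohort, c(config$simulate, list(seed = seed)))
    cohort <- sim$cohort
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(list(eta = sim$truth$eta, coef = as.list(sim$truth$coef),
                              block_of = as.list(sim$truth$block_of)),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (is.null(config$cohort_path)) stopf("no simulate stage and no cohort_path given")
    schema <- do.call(ct_schema, config$schema)
    cohort <- read_cohort(config$cohort_path, schema, standardize = "fit")
  }

  mc <- config$model %||% list()
  tc <- config$train %||% list()
  checkpoint <- NULL
  if ("pretrain" %in% stages) {
    pc <- config$pretrain %||% list()
    checkpoint <- pretrain(cohort,
                           iters = pc$iters %||% 2000L,
                           batch_size = pc$batch_size %||% 64L,
                           lr = pc$lr %||% 1e-3,
                           seed = seed)
    checkpoint_save(checkpoint, file.path(out_dir, "checkpoint"))
  }

  fit <- NULL
  if ("train" %in% stages) {
    splits <- make_splits(cohort, n_splits = tc$n_splits %||% 10L,
                          train_frac = tc$train_frac %||% 0.8, seed = seed)
    splits_save(splits, file.path(out_dir, "splits.json"))
    fit <- fine_tune(cohort, splits, checkpoint = checkpoint,
                     epochs = tc$epochs %||% 30L,
                     batch_size = tc$batch_size %||% 64L,
                     lr = tc$lr %||% 1e-3,
                     d_k = mc$d_k %||% 64L, n_layers = mc$n_layers %||% 2L,
                     n_heads = mc$n_heads %||% 4L, seed = seed)
    utils::write.csv(fit$curves, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    scores <- predict_scores(fit$models[[1L]], cohort)
    utils::write.csv(data.frame(patient_id = cohort$id, beta = scores),
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
  }

  if ("explain" %in% stages) {
    if (is.null(fit)) stopf("explain stage requires the train stage")
    ec <- config$explain %||% list()
    model <- fit$models[[1L]]
    test_idx <- fit$splits[[1L]]$test
    imp <- permutation_importance(model, cohort, idx = test_idx,
                                  n_repeats = ec$n_repeats %||% 10L, seed = seed)
    utils::write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
    im <- interaction_matrix(model, cohort)
    utils::write.csv(as.data.frame(im$S), file.path(out_dir, "interactions.csv"))
    groups <- cluster_functional_groups(im, n_groups = ec$n_groups, seed = seed)
    jsonlite::write_json(lapply(groups, unclass), file.path(out_dir, "groups.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("perturb" %in% stages) {
    if (is.null(fit)) stopf("perturb stage requires the train stage")
    pc <- config$perturb %||% list()
    feature <- pc$feature %||% colnames(cohort$tab)[1L]
    model <- fit$models[[1L]]
    pert <- perturb_single(model, cohort, feature, n_grid = pc$n_grid %||% 10L)
    traj <- data.frame(patient_id = rep(cohort$id, length(pert$grid)),
                       feature = feature,
                       grid_value = rep(pert$grid, each = length(cohort$id)),
                       beta = as.vector(pert$beta))
    utils::write.csv(traj, file.path(out_dir, "perturbation.csv"), row.names = FALSE)
    beta_all <- predict_scores(model, cohort)
    quart <- stratify_quartiles(beta_all)
    sp <- split_variant_invariant(pert$delta_beta,
                                  filter_idx = which(quart %in% c("Q1", "Q2")))
    pops <- data.frame(patient_id = cohort$id,
                       population = ifelse(seq_along(cohort$id) %in% sp$variant, "variant",
                                    ifelse(seq_along(cohort$id) %in% sp$invariant,
                                           "invariant", "excluded")))
    utils::write.csv(pops, file.path(out_dir, "populations.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
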