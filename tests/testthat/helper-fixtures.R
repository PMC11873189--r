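# shared fixtures, built in code

# a tiny deterministic cohort with mixed types and one missing cell
toy_cohort_df <- function() {
  data.frame(
    pid = c("a", "b", "c"),
    os_months = c(5, 12, 30),
    death = c(1L, 1L, 0L),
    tmb = c(12.1, NA, 3.3),
    msi = c(0L, 1L, 0L),
    cancer = c("lung", "skin", "colon"),
    stringsAsFactors = FALSE
  )
}

toy_schema <- function() {
  ct_schema(id = "pid", time = "os_months", event = "death",
            features = c(tmb = "continuous", msi = "binary",
                         cancer = "categorical"))
}

# brute-force pairwise oracles, written independently of the implementation
brute_survival_loss <- function(beta, time, event, sigma) {
  n <- length(beta); num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (event[i] == 1 && time[i] < time[j]) den <- den + 1
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (event[i] == 1 && time[i] < time[j])
      num <- num + 1 / (1 + exp((beta[j] - beta[i]) / sigma))
  }
  num / den
}

brute_c_index <- function(beta, time, event) {
  n <- length(beta); conc <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (beta[i] < beta[j]) conc <- conc + 1
      else if (beta[i] == beta[j]) conc <- conc + 0.5
    }
  }
  conc / den
}

# small trained model shared by model-dependent tests (trained once per run)
.fixture_env <- new.env(parent = emptyenv())

small_trained_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  sim <- simulate_cohort(160, blocks = list(list(size = 6, rho = 0)),
                         coef = c(b1_f1 = 0.9, b1_f2 = -0.9),
                         censor_frac = 0.25, seed = 41)
  splits <- make_splits(sim$cohort, n_splits = 1, seed = 41)
  fit <- fine_tune(sim$cohort, splits, epochs = 10, batch_size = 32,
                   d_k = 32, n_layers = 2, n_heads = 4, seed = 41)
  .fixture_env$fit <- list(sim = sim, splits = splits, fit = fit,
                           model = fit$models[[1]])
  .fixture_env$fit
}
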