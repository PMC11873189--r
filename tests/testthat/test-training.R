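test_that("splits are disjoint 80/20 partitions, seeded and serializable", {
  co <- simulate_cohort(100, blocks = list(list(size = 3, rho = 0)), seed = 1)$cohort
  sp <- make_splits(co, n_splits = 10, seed = 7)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(s$train, 80)
    expect_length(s$test, 20)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), 1:100)
  }
  expect_identical(sp, make_splits(co, n_splits = 10, seed = 7))
  expect_warning(make_splits(co, n_splits = 2, train_frac = 1, seed = 1), "empty")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  splits_save(sp, p1)
  splits_save(make_splits(co, n_splits = 10, seed = 7), p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-for-byte reuse
  expect_identical(splits_load(p1), sp)
})

test_that("an untrained zero-head model scores every patient 0", {
  co <- simulate_cohort(20, blocks = list(list(size = 3, rho = 0)), seed = 2)$cohort
  vocab <- ct_vocab(co)
  config <- ct_config(vocab$size, compute_max_length(co, 95), d_k = 16,
                      n_layers = 1, n_heads = 2, ff_dim = 16)
  model <- structure(list(params = ct_init(config, seed = 1), config = config,
                          vocab = vocab), class = "ct_model")
  expect_equal(predict_scores(model, co), rep(0, 20))
})

test_that("prediction is deterministic, order-free, and tolerates empty records", {
  f <- small_trained_fit()
  model <- f$model; co <- f$sim$cohort
  b1 <- predict_scores(model, co)
  expect_identical(b1, predict_scores(model, co))
  # column-shuffled cohort: identical scores within 1e-5
  perm <- sample(ncol(co$tab))
  co_shuf <- co; co_shuf$tab <- co$tab[, perm]
  co_shuf$schema$features <- co$schema$features[perm]
  expect_equal(predict_scores(model, co_shuf), b1, tolerance = 1e-5)
  # a patient with every feature missing scores from the TASK token alone
  co_empty <- co
  co_empty$tab[1, ] <- NA_real_
  b <- predict_scores(model, co_empty)
  expect_true(is.finite(b[1]))
})

test_that("truncated records are scored by a seeded subsample average, reproducibly", {
  sim <- simulate_cohort(12, blocks = list(list(size = 20, rho = 0)),
                         coef = c(b1_f1 = 0.8), censor_frac = 0.2, seed = 3)
  co <- sim$cohort
  vocab <- ct_vocab(co)
  config <- ct_config(vocab$size, max_len = 9L, d_k = 16, n_layers = 1,
                      n_heads = 2, ff_dim = 16)
  params <- ct_init(config, seed = 4)
  set.seed(8); params$w_surv <- rnorm(16) * 0.2
  model <- structure(list(params = params, config = config, vocab = vocab),
                     class = "ct_model")
  s1 <- predict_scores(model, co)
  s2 <- predict_scores(model, co)
  expect_identical(s1, s2)
})

test_that("fine-tuning learns a strong linear hazard and records learning curves", {
  f <- small_trained_fit()
  curves <- f$fit$curves
  expect_equal(sort(unique(curves$split)), 1)
  expect_equal(max(curves$epoch), 10)
  oracle <- c_index(-f$sim$truth$eta[f$splits[[1]]$test],
                    f$sim$cohort$time[f$splits[[1]]$test],
                    f$sim$cohort$event[f$splits[[1]]$test])
  # the model should capture a good share of the attainable concordance
  expect_gt(tail(curves$c_index, 1), 0.60)
  expect_lte(tail(curves$c_index, 1), oracle + 0.05)
})

test_that("pretraining with zero iterations returns the initialization unchanged", {
  co <- simulate_cohort(30, blocks = list(list(size = 4, rho = 0)), seed = 5)$cohort
  ck <- pretrain(co, iters = 0, seed = 11)
  expect_equal(ck$params, ct_init(ck$config, seed = 11), ignore_attr = TRUE)
  expect_equal(nrow(ck$history), 0)
})

test_that("masked-name prediction on a co-occurrence cohort beats chance by 5x", {
  cc <- make_cooccurrence_cohort(240, n_pairs = 4, n_background = 2, seed = 6)
  co <- cc$cohort
  cfg <- ct_config(ct_vocab(co)$size, compute_max_length(co, 100),
                   d_k = 32, n_layers = 2, n_heads = 4, ff_dim = 64)
  ck <- pretrain(co, config = cfg, iters = 600, batch_size = 32, lr = 1e-3,
                 seed = 6)
  # evaluate masked-name accuracy on pair features
  vocab <- ck$vocab
  records <- as_records(co)
  correct <- 0L; total <- 0L
  set.seed(7)
  for (i in sample(240, 60)) {
    row <- sample_and_pad(records[[i]], cfg$max_len, vocab, shuffle = FALSE)
    # mask the B member of the patient's pair; its A partner stays visible
    k <- cc$truth$pair_of[i]
    bpos <- which(row$token_ids == vocab$feature_ids[sprintf("B%d", k)])
    truth_class <- row$token_ids[bpos] - vocab$n_reserved
    row$token_ids[bpos] <- vocab$mask_id
    batch <- list(token_ids = matrix(row$token_ids, 1),
                  values = matrix(row$values, 1), pad = matrix(row$pad, 1))
    fwd <- ct_forward(ck$params, cfg, batch)
    pred <- which.max(masked_heads(ck$params, fwd$P[bpos, , drop = FALSE])$probs)
    correct <- correct + (pred == truth_class); total <- total + 1L
  }
  acc <- correct / total
  chance <- 1 / length(vocab$feature_ids)
  expect_gt(acc, 5 * chance)
})

test_that("quartile stratification uses train cutoffs; median split and degenerate cases work", {
  lab <- stratify_quartiles(1:100, c(10, 30, 60, 90))
  expect_equal(as.character(lab), c("Q1", "Q2", "Q3", "Q4"))
  lab2 <- stratify_quartiles(1:100, c(10, 90), n_groups = 2)
  expect_equal(as.character(lab2), c("Q1", "Q2"))
  expect_warning(labd <- stratify_quartiles(rep(1, 10)), "single group")
  expect_true(all(labd == "Q1"))
})

test_that("checkpoint save/load/predict round-trips scores exactly", {
  f <- small_trained_fit()
  dir <- withr::local_tempdir()
  checkpoint_save(f$model, dir)
  back <- checkpoint_load(dir)
  expect_identical(predict_scores(back, f$sim$cohort),
                   predict_scores(f$model, f$sim$cohort))
})

test_that("fine-tuning from a checkpoint requires a covering vocabulary", {
  co <- simulate_cohort(40, blocks = list(list(size = 3, rho = 0)), seed = 8)$cohort
  ck <- pretrain(co, iters = 0, seed = 1)
  other <- simulate_cohort(40, blocks = list(list(size = 5, rho = 0)), seed = 9)$cohort
  expect_error(fine_tune(other, make_splits(other, 1, seed = 1), checkpoint = ck),
               "vocabulary")
})
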