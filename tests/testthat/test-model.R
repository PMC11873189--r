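# small config used throughout: 2 layers, 2 heads, d_k 16
tiny_setup <- function(n = 8, seed = 21, dropout = 0) {
  sim <- simulate_cohort(n, blocks = list(list(size = 5, rho = 0)),
                         n_mut = 2, censor_frac = 0.2, miss_frac = 0.15,
                         seed = seed)
  vocab <- ct_vocab(sim$cohort)
  config <- ct_config(vocab$size, compute_max_length(sim$cohort, 100),
                      d_k = 16, n_layers = 2, n_heads = 2, ff_dim = 24,
                      dropout = dropout)
  params <- ct_init(config, seed = seed)
  list(cohort = sim$cohort, vocab = vocab, config = config, params = params,
       records = as_records(sim$cohort))
}

test_that("input embeddings are additive in name and value, with no positional term", {
  s <- tiny_setup()
  batch <- encode_batch(s$records[1:3], s$config$max_len, s$vocab, shuffle = FALSE)
  # zero value projection: embedding reduces to the pure name lookup
  p0 <- s$params; p0$w_val[] <- 0
  E <- embed_inputs(p0, batch)
  expect_equal(E[1, ], unname(p0$Emb[s$vocab$task_id, ]))
  # doubling a value moves only that position, linearly along w_val
  b2 <- batch
  b2$values[1, 2] <- 2 * batch$values[1, 2]
  E1 <- embed_inputs(s$params, batch); E2 <- embed_inputs(s$params, b2)
  diffs <- which(rowSums(abs(E2 - E1)) > 0)
  expect_equal(diffs, 2L)
  expect_equal(E2[2, ] - E1[2, ], batch$values[1, 2] * s$params$w_val)
  # out-of-range token id is fatal
  bad <- batch; bad$token_ids[1, 2] <- s$vocab$size + 5L
  expect_error(embed_inputs(s$params, bad), "out of vocabulary")
})

test_that("two column orders of the same record give the same embedding multiset", {
  s <- tiny_setup()
  rec <- s$records[[1]]
  rec_rev <- rec; rec_rev$features <- rev(rec$features)
  b1 <- encode_batch(list(rec), s$config$max_len, s$vocab, shuffle = FALSE)
  b2 <- encode_batch(list(rec_rev), s$config$max_len, s$vocab, shuffle = FALSE)
  # deterministic encoding canonicalizes order, so rows must be identical
  expect_identical(b1, b2)
})

test_that("attention rows are stochastic over non-PAD columns at every layer and head", {
  s <- tiny_setup()
  batch <- encode_batch(s$records, s$config$max_len, s$vocab, shuffle = FALSE)
  fwd <- ct_forward(s$params, s$config, batch, return_attention = TRUE)
  H <- s$config$n_heads; L <- s$config$max_len
  for (l in seq_len(s$config$n_layers)) {
    A <- fwd$attention[[l]]
    for (b in seq_len(nrow(batch$token_ids))) {
      pad_cols <- which(batch$pad[b, ])
      for (h in seq_len(H)) {
        Ah <- A[, , (b - 1) * H + h]
        expect_equal(rowSums(Ah), rep(1, L), tolerance = 1e-5)
        if (length(pad_cols)) expect_true(all(Ah[, pad_cols] == 0))
      }
    }
  }
})

test_that("a patient with a single feature attends only to its two non-PAD columns", {
  s <- tiny_setup()
  rec <- s$records[[1]]
  rec$features <- rec$features[1]
  batch <- encode_batch(list(rec), s$config$max_len, s$vocab, shuffle = FALSE)
  fwd <- ct_forward(s$params, s$config, batch, return_attention = TRUE)
  A1 <- fwd$attention[[1]][, , 1]
  expect_equal(rowSums(A1[, 1:2]), rep(1, s$config$max_len), tolerance = 1e-6)
})

test_that("permuting input feature positions permutes embeddings and fixes the score", {
  s <- tiny_setup(n = 6)
  # train a couple of steps so weights are not at init
  co <- s$cohort
  splits <- list(list(train = 1:6, test = integer(0)))
  fit <- fine_tune(co, splits, config = s$config, epochs = 3, batch_size = 6,
                   seed = 3)
  model <- fit$models[[1]]
  rec <- as_records(co)[[2]]
  base <- encode_batch(list(rec), s$config$max_len, s$vocab, shuffle = FALSE)
  fwd0 <- ct_forward(model$params, model$config, base)
  for (r in 1:5) {
    perm_row <- sample_and_pad(rec, s$config$max_len, s$vocab, shuffle = TRUE,
                               seed = r)
    pb <- list(token_ids = matrix(perm_row$token_ids, 1),
               values = matrix(perm_row$values, 1),
               pad = matrix(perm_row$pad, 1))
    fwdp <- ct_forward(model$params, model$config, pb)
    # TASK embedding (and hence beta) invariant
    expect_equal(fwdp$P[1, ], fwd0$P[1, ], tolerance = 1e-5)
    # feature rows permuted identically with their tokens
    m <- match(perm_row$token_ids, base$token_ids[1, ])
    expect_equal(fwdp$P[!perm_row$pad, ], fwd0$P[m[!perm_row$pad], ],
                 tolerance = 1e-5)
  }
})

test_that("a zero-weight encoder reproduces a hand-rolled residual/normalization path", {
  s <- tiny_setup()
  p <- s$params
  for (l in 1:2) for (w in c("Wq", "Wk", "Wv", "Wo", "W1", "W2"))
    p[[paste0(w, l)]][] <- 0
  batch <- encode_batch(s$records[1:2], s$config$max_len, s$vocab, shuffle = FALSE)
  fwd <- ct_forward(p, s$config, batch)
  # independent oracle: with all projections zero, each block reduces to two
  # successive layer norms of the input embedding
  E <- p$Emb[as.vector(t(batch$token_ids)), ] +
    outer(as.vector(t(batch$values)), p$w_val)
  ln <- function(x) {
    t(apply(x, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6)))
  }
  expected <- ln(ln(ln(ln(E))))
  expect_equal(fwd$P, expected, tolerance = 1e-10)
})

test_that("survival head is an exact bias-free dot product", {
  s <- tiny_setup()
  p <- s$params
  P_task <- matrix(rnorm(3 * 16), 3, 16)
  p$w_surv[] <- 0
  expect_equal(survival_head(p, P_task), c(0, 0, 0))
  p$w_surv <- c(2, rep(0, 15))
  e1 <- diag(16)[1, , drop = FALSE]
  expect_equal(survival_head(p, e1), 2)
  set.seed(5)
  p$w_surv <- rnorm(16)
  expect_equal(survival_head(p, P_task),
               apply(P_task, 1, function(r) sum(r * p$w_surv)))
})

test_that("masked heads emit normalized name probabilities and linear values", {
  s <- tiny_setup()
  Pm <- matrix(rnorm(4 * 16), 4, 16)
  h <- masked_heads(s$params, Pm)
  expect_equal(rowSums(h$probs), rep(1, 4), tolerance = 1e-6)
  # equal logits -> uniform over the feature vocabulary
  p <- s$params; p$W_name[] <- 0; p$b_name[] <- 0
  h0 <- masked_heads(p, Pm)
  Vf <- s$vocab$size - 3
  expect_equal(h0$probs, matrix(1 / Vf, 4, Vf), tolerance = 1e-12)
  expect_error(masked_heads(s$params, matrix(0, 0, 16)), "no masked positions")
})

test_that("backpropagation matches finite differences through the whole network", {
  s <- tiny_setup(n = 5)
  p <- s$params
  set.seed(77)
  p$w_surv <- rnorm(16) * 0.3
  batch <- encode_batch(s$records[1:5], s$config$max_len, s$vocab, shuffle = FALSE)
  time <- s$cohort$time[1:5]; event <- s$cohort$event[1:5]
  lossfun <- function(pp) {
    f <- ct_forward(pp, s$config, batch)
    survival_loss(survival_head(pp, f$P[f$task_rows, , drop = FALSE]),
                  time, event, sigma = 0.5)
  }
  fwd <- ct_forward(p, s$config, batch, keep_cache = TRUE)
  beta <- survival_head(p, fwd$P[fwd$task_rows, , drop = FALSE])
  sl <- survival_loss(beta, time, event, sigma = 0.5, gradient = TRUE)
  g <- clinformer:::grad_zeros(p)
  g$w_surv <- colSums(fwd$P[fwd$task_rows, , drop = FALSE] * sl$grad)
  dP <- matrix(0, nrow(fwd$P), 16)
  dP[fwd$task_rows, ] <- outer(sl$grad, p$w_surv)
  g <- ct_backward(p, s$config, fwd, dP, g)
  set.seed(99)
  for (nm in c("Emb", "w_val", "w_surv", "Wq1", "Wk1", "Wv2", "Wo1",
               "ln1g1", "ln2b2", "W11", "b12", "W22")) {
    for (ii in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      e <- 1e-6
      pp <- p; pp[[nm]][ii] <- p[[nm]][ii] + e; up <- lossfun(pp)
      pp[[nm]][ii] <- p[[nm]][ii] - e; dn <- lossfun(pp)
      num <- (up - dn) / (2 * e)
      ana <- g[[nm]][ii]
      if (max(abs(num), abs(ana)) > 1e-8)
        expect_equal(ana, num, tolerance = 1e-4,
                     label = sprintf("grad %s[%d]", nm, ii))
    }
  }
  # PAD slots carry exactly zero value-gradient: perturbing a PAD value is a no-op
  b2 <- batch
  pad_pos <- which(batch$pad, arr.ind = TRUE)[1, ]
  b2$values[pad_pos[1], pad_pos[2]] <- 99
  expect_equal(lossfun_pad <- {
    f <- ct_forward(p, s$config, b2)
    survival_loss(survival_head(p, f$P[f$task_rows, , drop = FALSE]),
                  time, event, sigma = 0.5)
  }, lossfun(p))
})

test_that("checkpoints round-trip weights, config, and vocabulary", {
  s <- tiny_setup()
  model <- structure(list(params = s$params, config = s$config, vocab = s$vocab),
                     class = "ct_model")
  dir <- withr::local_tempdir()
  checkpoint_save(model, dir)
  back <- checkpoint_load(dir)
  expect_equal(back$params, s$params, ignore_attr = TRUE)
  expect_equal(unclass(back$config), unclass(s$config))
  expect_equal(back$vocab$feature_ids, s$vocab$feature_ids)
  batch <- encode_batch(s$records[1:3], s$config$max_len, s$vocab, shuffle = FALSE)
  expect_identical(ct_forward(back$params, back$config, batch)$P,
                   ct_forward(s$params, s$config, batch)$P)
})

test_that("model configuration rejects head counts that do not divide d_k", {
  expect_error(ct_config(10, 5, d_k = 16, n_heads = 3), "divisible")
})
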