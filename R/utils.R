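# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards. `seed = NULL` means: use the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Row-wise softmax of a matrix; entries at -Inf (or <= .mask_value) get 0.
row_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# large negative used to mask PAD columns before softmax (avoids -Inf - -Inf NaNs)
.MASK_NEG <- -1e30

# add a length-ncol row vector to every row (cheaper than sweep on hot paths)
add_row <- function(X, v) X + rep(v, each = nrow(X))

# multiply every row element-wise by a length-ncol vector
mul_row <- function(X, v) X * rep(v, each = nrow(X))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# linear-interpolation percentile (type 7), the package-wide convention
pctl <- function(x, p) as.numeric(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
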