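# Internal numeric helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package route
# through this so that outputs are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Linear-interpolation percentile (quantile type 7) of all values.
pctl <- function(x, p) {
  stats::quantile(as.numeric(x), probs = p / 100, names = FALSE, type = 7)
}

# Left-right mirror of a planar pixel matrix. By package convention the first
# matrix dimension is the patient left-right axis.
mirror_lr <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

# Bilinear sample of matrix `m` at continuous 1-based (row, col) positions.
# Positions outside the grid are clamped to the border.
bilinear_at <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc +
    m[cbind(r1, c1)] * fr * fc
}

is_binary <- function(x) {
  v <- as.numeric(x)
  all(is.finite(v)) && all(v == 0 | v == 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
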