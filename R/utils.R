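# Internal numerical helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`; caller's stream is
# untouched. All stochastic operations in the package route through this.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Centered moving average with edge shrinkage: the window shrinks to the
# available samples so output length equals input length. For even widths the
# window spans floor((w-1)/2) samples back and ceiling((w-1)/2) forward.
moving_average <- function(x, width) {
  n <- length(x)
  stopifnot(width >= 1, width <= n)
  b <- floor((width - 1) / 2)
  f <- ceiling((width - 1) / 2)
  bad <- !is.finite(x)
  cs <- cumsum(c(0, ifelse(bad, 0, x)))
  cn <- cumsum(c(0, bad))
  t <- seq_len(n)
  lo <- pmax(1L, t - b)
  hi <- pmin(n, t + f)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out[(cn[hi + 1L] - cn[lo]) > 0] <- NaN   # window touched a flagged sample
  out
}

# Zero-phase smoothing with an arbitrary symmetric kernel; edges renormalize
# the kernel over the available support (no phase shift, no attenuation).
smooth_kernel <- function(x, kernel) {
  n <- length(x)
  k <- (length(kernel) - 1L) %/% 2L
  stopifnot(length(kernel) == 2L * k + 1L)
  xp <- c(rep(0, k), x, rep(0, k))
  wp <- c(rep(0, k), rep(1, n), rep(0, k))
  num <- stats::filter(xp, kernel, sides = 2)
  den <- stats::filter(wp, kernel, sides = 2)
  as.numeric(num[(k + 1L):(k + n)] / den[(k + 1L):(k + n)])
}

gaussian_kernel <- function(width_s) {
  k <- max(1L, as.integer(round(width_s)))
  g <- stats::dnorm(seq(-k, k), sd = width_s / 2)
  g / sum(g)
}

# Nearest correlation matrix by alternating projections (PSD cone <-> unit
# diagonal). Adequate for the mild indefiniteness of sign-pattern presets.
nearest_correlation <- function(R, tol = 1e-10, max_iter = 500L) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  Y <- (R + t(R)) / 2
  for (i in seq_len(max_iter)) {
    e <- eigen(Y, symmetric = TRUE)
    X <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    X <- (X + t(X)) / 2
    diag(X) <- 1
    if (max(abs(X - Y)) < tol) return(X)
    Y <- X
  }
  Y
}

is_psd <- function(R, tol = 1e-8) {
  min(eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

matrix_sqrt <- function(R) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
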