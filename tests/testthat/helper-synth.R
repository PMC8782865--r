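# Shared fixture builders: everything is generated in code at test time.

# Single-state generator spec with an arbitrary target correlation.
one_state_spec <- function(duration_s, R = diag(6), seed = 1L, ...) {
  generator_spec(list(list(label = "s1", duration_s = duration_s,
                           target_R = R)),
                 seed = seed, ...)
}

# 6x6 correlation matrix with a single coupled pair.
pair_R <- function(i, j, rho) {
  R <- diag(6)
  R[i, j] <- R[j, i] <- rho
  R
}

# Envelope-level smoothed series ready for coupling analysis.
smoothed_series <- function(spec, subject_id = "S01", test_id = "T1") {
  smooth_band_power(band_weight_series(spec, subject_id = subject_id,
                                       test_id = test_id), 14)
}

# Group-pooled fit over n_subjects x n_tests protocol realizations of the
# exercise-like preset (envelope level), mirroring the pooled group analysis.
group_fit <- function(seed, n_subjects = 19, n_tests = 2) {
  bps <- list()
  for (s in seq_len(n_subjects)) for (tt in seq_len(n_tests)) {
    sp <- sana_preset("exercise_like",
                      seed = seed * 100000L + s * 100L + tt)
    bps[[length(bps) + 1L]] <- band_weight_series(
      sp, subject_id = sprintf("S%02d", s), test_id = paste0("T", tt))
  }
  sana(bps)
}

# Effective decorrelation time of the generator's smoothed modulators:
# tau = sum over lags of the squared autocorrelation of the smoothing kernel
# output. Sampling sd of an empirical zero correlation over T samples is
# ~ sqrt(tau / T); used to set principled tolerance bands.
envelope_tau <- function(width_s = 10) {
  g <- sana:::gaussian_kernel(width_s)
  cc <- stats::convolve(g, g, type = "open")
  rho <- cc / max(cc)
  sum(rho^2)
}

# Minimal coupling_windows-like object from explicit values (for summary
# helpers that only need the long-format columns).
fake_windows <- function(C, p = NULL, pair = "delta-theta", state = "s1",
                         subject_id = "S01", test_id = "T1") {
  ij <- sana:::resolve_pair(pair)
  d <- data.frame(subject_id = subject_id, test_id = test_id, channel = "X",
                  state = state, window_index = seq_along(C), start_s = 0,
                  i = ij[1], j = ij[2], pair = pair, C = C,
                  p = p %||% rep(0.5, length(C)), valid = is.finite(C),
                  stringsAsFactors = FALSE)
  attr(d, "config") <- analysis_config()
  class(d) <- c("coupling_windows", "data.frame")
  d
}

# degree_matrices object with a prescribed value on every off-diagonal.
fake_degree <- function(dp, dm, state = "s1") {
  Dp <- matrix(dp, 6, 6); Dm <- matrix(dm, 6, 6)
  diag(Dp) <- diag(Dm) <- 0
  dimnames(Dp) <- dimnames(Dm) <- list(rhythms(), rhythms())
  structure(list(D_plus = Dp, D_minus = Dm,
                 n = matrix(100, 6, 6), state = state, channel = "X",
                 threshold = 0.5),
            class = "degree_matrices")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
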