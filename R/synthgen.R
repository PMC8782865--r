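# Synthetic coupled-rhythm generator. Latent jointly-Gaussian modulators with
# a prescribed zero-lag 6x6 correlation per state are mapped through a softmax
# onto the 6-simplex of relative band weights; EEG is then synthesized as
# band-limited unit-power carriers amplitude-modulated by sqrt(weights), plus
# a broadband noise floor. Because every modulator is smoothed with the SAME
# zero-phase kernel, the target correlation structure survives smoothing
# exactly (in expectation); the softmax distorts magnitudes but preserves
# signs and ordering, which is what the downstream analysis measures.

#' Specify the synthetic coupled-rhythm generator
#'
#' @param states A list of states, each a list with `label`, `duration_s`, and
#'   `target_R` (6x6 symmetric, unit-diagonal, positive semi-definite
#'   correlation matrix for the latent envelope modulators).
#' @param baseline_weights Six positive baseline relative band powers summing
#'   to 1 (order [rhythms()]). The default is a realistic resting scalp
#'   profile dominated by delta/alpha.
#' @param modulation_depth Dimensionless softmax gain applied to the latent
#'   modulators; 0 freezes the weights at the baseline.
#' @param envelope_timescale_s Width (seconds) of the truncated-Gaussian
#'   zero-phase kernel smoothing the modulators; sets the envelope
#'   autocorrelation time (default 10 s, a few waves per 100 s segment).
#' @param noise_floor Broadband noise power as a fraction of signal power.
#' @param sample_rate_hz EEG synthesis rate; must be at least twice the top
#'   gamma edge (49 Hz).
#' @param seed Integer seed; every stochastic step derives from it.
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(states,
                           baseline_weights = c(0.30, 0.18, 0.22, 0.12, 0.10, 0.08),
                           modulation_depth = 1,
                           envelope_timescale_s = 10,
                           noise_floor = 0.1,
                           sample_rate_hz = 250,
                           seed = 1L) {
  if (!is.list(states) || length(states) < 1)
    stop("at least one state is required")
  for (s in states) {
    if (!all(c("label", "duration_s", "target_R") %in% names(s)))
      stop("each state needs label, duration_s, target_R")
    R <- s$target_R
    if (!is.matrix(R) || any(dim(R) != 6))
      stop("state '", s$label, "': target_R must be 6x6")
    if (max(abs(R - t(R))) > 1e-10)
      stop("state '", s$label, "': target_R must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-10)
      stop("state '", s$label, "': target_R must have unit diagonal")
    if (!is_psd(R))
      stop("state '", s$label, "': target_R is not positive semi-definite")
    if (s$duration_s < envelope_timescale_s)
      stop("state '", s$label, "': duration shorter than envelope_timescale_s")
  }
  stopifnot(length(baseline_weights) == 6, all(baseline_weights > 0))
  if (abs(sum(baseline_weights) - 1) > 1e-12)
    stop("baseline_weights must sum to 1")
  stopifnot(modulation_depth >= 0, envelope_timescale_s > 0, noise_floor >= 0)
  if (sample_rate_hz < 2 * max(band_definitions()$f_hi))
    stop("sample_rate_hz must be at least twice the top band edge (49 Hz)")
  structure(
    list(states = states, baseline_weights = baseline_weights,
         modulation_depth = modulation_depth,
         envelope_timescale_s = envelope_timescale_s,
         noise_floor = noise_floor, sample_rate_hz = sample_rate_hz,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Build a target correlation matrix from a sign pattern
#'
#' Fills the 6x6 latent correlation matrix with `delta_anti` for all five
#' delta pairs, `sbg_positive` for the sigma-beta, sigma-gamma and beta-gamma
#' pairs, `theta_alpha` for the theta-alpha pair, and `mixed` for the six
#' remaining theta/alpha pairs (state-switching class). Strong patterns of
#' this shape are typically not positive semi-definite, so by default the
#' matrix is projected to the nearest correlation matrix, which preserves
#' the sign pattern while making the target attainable.
#'
#' @param delta_anti,sbg_positive,theta_alpha,mixed Pattern entries.
#' @param project Project to the nearest valid correlation matrix (default).
#' @return A 6x6 correlation matrix with [rhythms()] dimnames.
#' @export
target_correlation <- function(delta_anti = -0.7, sbg_positive = 0.7,
                               theta_alpha = 0, mixed = 0, project = TRUE) {
  R <- matrix(0, 6, 6, dimnames = list(.rhythms, .rhythms))
  R[1, 2:6] <- R[2:6, 1] <- delta_anti
  for (p in list(c(4, 5), c(4, 6), c(5, 6)))
    R[p[1], p[2]] <- R[p[2], p[1]] <- sbg_positive
  for (p in list(c(2, 4), c(2, 5), c(2, 6), c(3, 4), c(3, 5), c(3, 6)))
    R[p[1], p[2]] <- R[p[2], p[1]] <- mixed
  R[2, 3] <- R[3, 2] <- theta_alpha
  diag(R) <- 1
  if (project && !is_psd(R)) {
    R <- nearest_correlation(R)
    dimnames(R) <- list(.rhythms, .rhythms)
  }
  R
}

#' Preset generator specifications
#'
#' `"exercise_like"` is the five-state protocol template (rest 900 s, warm-up
#' 600 s, exercise 1800 s, cool-down 600 s, cognitive task 360 s) carrying the
#' three coupling classes: delta anti-correlated with every other rhythm and
#' sigma/beta/gamma mutually positive in every state, at state-dependent
#' strength (weakest at rest, strongest during exercise); the seven
#' theta/alpha mixed pairs switch sign with state — mildly negative at rest
#' and during the cognitive task, positive in the active states — emulating
#' the stratification of coupling strength across physiological states.
#' `"null"` keeps the same protocol but with independent modulators
#' (identity target) in every state.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [generator_spec()] (e.g. `seed`,
#'   `noise_floor`, `sample_rate_hz`).
#' @return A `"generator_spec"`.
#' @export
sana_preset <- function(name = c("exercise_like", "null"), ...) {
  name <- match.arg(name)
  labels <- c("rest", "warm_up", "exercise", "cool_down", "cognitive")
  durations <- c(900, 600, 1800, 600, 360)
  if (name == "exercise_like") {
    strength <- c(0.5, 0.7, 1.0, 0.7, 0.6)     # rest weakest, exercise strongest
    ta <- c(-0.3, 0.3, 0.5, 0.3, -0.2)         # theta-alpha switches sign
    mx <- c(-0.2, 0.3, 0.4, 0.3, -0.2)         # other mixed pairs switch sign
    states <- lapply(seq_along(labels), function(k) list(
      label = labels[k], duration_s = durations[k],
      target_R = target_correlation(delta_anti = -0.7 * strength[k],
                                    sbg_positive = 0.7 * strength[k],
                                    theta_alpha = ta[k], mixed = mx[k])
    ))
  } else {
    states <- lapply(seq_along(labels), function(k) list(
      label = labels[k], duration_s = durations[k],
      target_R = diag(6)
    ))
  }
  generator_spec(states, ...)
}

#' Draw correlated latent envelope modulators
#'
#' Per state, six i.i.d. standard-normal series are mixed by a symmetric
#' square root of the state's target correlation and every series is smoothed
#' with the same zero-phase truncated-Gaussian kernel, then rescaled to unit
#' interior variance. Same-kernel smoothing of jointly white inputs preserves
#' the instantaneous (zero-lag) correlation, so the output correlation equals
#' the target up to sampling error. Deterministic given the spec seed.
#'
#' @param spec A [generator_spec()].
#' @return An object of class `"modulator_series"`: a 6 x T matrix at one
#'   sample per second plus per-sample state labels.
#' @export
make_modulators <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  g <- gaussian_kernel(spec$envelope_timescale_s)
  sd_factor <- sqrt(sum(g^2))
  with_seed(spec$seed, {
    pieces <- lapply(spec$states, function(s) {
      T_s <- as.integer(round(s$duration_s))
      A <- matrix_sqrt(s$target_R)
      M <- A %*% matrix(stats::rnorm(6L * T_s), nrow = 6L)
      M <- t(apply(M, 1, smooth_kernel, kernel = g)) / sd_factor
      list(values = M, states = rep(s$label, T_s))
    })
    structure(
      list(values = do.call(cbind, lapply(pieces, `[[`, "values")),
           states = unlist(lapply(pieces, `[[`, "states")),
           spec = spec),
      class = "modulator_series"
    )
  })
}

#' Map latent modulators to relative band weights
#'
#' Softmax map `w_i(t) = b_i exp(depth * m_i(t)) / sum_j b_j exp(depth *
#' m_j(t))`: every column lies strictly inside the 6-simplex and sums to 1,
#' and each weight is strictly increasing in its own modulator. `depth = 0`
#' returns the baseline weights at every sample.
#'
#' @param m A `"modulator_series"`.
#' @param baseline_weights,modulation_depth Defaults taken from the spec
#'   carried by `m`.
#' @param subject_id,test_id,channel Tags written into the annotations.
#' @return A relative-mode band-power series (see [band_power()]).
#' @export
modulators_to_band_weights <- function(m, baseline_weights = NULL,
                                       modulation_depth = NULL,
                                       subject_id = "S01", test_id = "T1",
                                       channel = "SIM") {
  stopifnot(inherits(m, "modulator_series"))
  b <- baseline_weights %||% m$spec$baseline_weights
  depth <- modulation_depth %||% m$spec$modulation_depth
  stopifnot(length(b) == 6, all(b > 0), depth >= 0)
  if (!all(is.finite(m$values))) stop("non-finite modulators")
  E <- b * exp(depth * m$values)        # 6 x T, recycled by column
  W <- sweep(E, 2, colSums(E), "/")
  runs <- rle(m$states)
  ends <- cumsum(runs$lengths)
  ann <- session_annotations(runs$values, c(0, ends[-length(ends)]), ends,
                             subject_id = subject_id, test_id = test_id)
  band_power(W, mode = "relative", channel = channel, annotations = ann)
}

#' Generate an envelope-level band-power series in one call
#'
#' Convenience chain [make_modulators()] + [modulators_to_band_weights()]:
#' the generator's band-power output, bypassing EEG synthesis and spectral
#' estimation. Useful for testing the analysis stages at scale.
#'
#' @inheritParams make_modulators
#' @inheritParams modulators_to_band_weights
#' @param seed Optional seed override for this realization.
#' @return A relative-mode band-power series.
#' @export
band_weight_series <- function(spec, subject_id = "S01", test_id = "T1",
                               channel = "SIM", seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  modulators_to_band_weights(make_modulators(spec),
                             subject_id = subject_id, test_id = test_id,
                             channel = channel)
}

#' Synthesize multi-channel EEG from relative band weights
#'
#' Per channel, the signal is `sum_i a_i(t) x_i(t) + noise`, where each
#' carrier `x_i` is unit-power white noise band-pass filtered to band i with
#' a zero-phase FFT filter, `a_i(t) = sqrt(w_i(t))` linearly interpolated from
#' the 1 Hz weight grid to the sample rate, and the additive white noise power
#' is `noise_floor` times the signal power. Carriers are independent across
#' bands and channels (the method measures amplitude-amplitude coupling only,
#' so carrier phases are irrelevant). Deterministic given `seed`.
#'
#' @param weights A relative-mode band-power series.
#' @param spec The [generator_spec()] (rate, noise floor, seed).
#' @param channel_labels Channels to synthesize.
#' @param seed Optional seed override.
#' @return An `eeg_recording` carrying the weights' annotations.
#' @export
synthesize_eeg <- function(weights, spec, channel_labels = "C3", seed = NULL) {
  stopifnot(inherits(weights, "band_power"), inherits(spec, "generator_spec"))
  if (weights$mode != "relative") stop("weights must be a relative-mode series")
  W <- weights$values
  if (any(W < 0)) stop("negative weights")
  if (spec$sample_rate_hz < 2 * max(band_definitions()$f_hi))
    stop("sample rate below Nyquist of the gamma band")
  if (spec$noise_floor == 0 && any(colSums(W) == 0))
    stop("all-zero weights with a zero noise floor: nothing to synthesize")
  fs <- spec$sample_rate_hz
  T_s <- ncol(W)
  n <- as.integer(round(T_s * fs))
  t_hi <- (seq_len(n) - 1) / fs
  bands <- band_definitions()
  out <- matrix(0, nrow = length(channel_labels), ncol = n)
  with_seed(seed %||% spec$seed, {
    for (ch in seq_along(channel_labels)) {
      sig <- numeric(n)
      for (i in 1:6) {
        x <- fft_bandpass(stats::rnorm(n), fs, bands$f_lo[i], bands$f_hi[i])
        x <- x / stats::sd(x)
        a <- stats::approx(weights$time_s, sqrt(W[i, ]), xout = t_hi,
                           rule = 2)$y
        sig <- sig + a * x
      }
      if (spec$noise_floor > 0)
        sig <- sig + stats::rnorm(n, sd = sqrt(spec$noise_floor * stats::var(sig)))
      out[ch, ] <- sig
    }
  })
  recording(out, fs, channel_labels = channel_labels,
            annotations = weights$annotations)
}

#' Generate a full protocol recording
#'
#' Chains [make_modulators()], [modulators_to_band_weights()] and
#' [synthesize_eeg()] over the spec's state sequence, producing a contiguous
#' multi-session recording with its annotation table.
#'
#' @inheritParams synthesize_eeg
#' @inheritParams modulators_to_band_weights
#' @return A list with elements `recording` (an `eeg_recording`) and
#'   `annotations` (the session table).
#' @export
make_protocol_recording <- function(spec, channel_labels = "C3",
                                    subject_id = "S01", test_id = "T1") {
  w <- band_weight_series(spec, subject_id = subject_id, test_id = test_id)
  rec <- synthesize_eeg(w, spec, channel_labels = channel_labels)
  list(recording = rec, annotations = rec$annotations)
}

#' Serialize a generator spec to JSON (and back)
#'
#' @param spec A `"generator_spec"`.
#' @param path File path.
#' @export
write_generator_spec <- function(spec, path) {
  x <- unclass(spec)
  x$states <- lapply(x$states, function(s) {
    s$target_R <- unname(s$target_R); s
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- lapply(seq_len(nrow(x$states)), function(k) list(
    label = x$states$label[k],
    duration_s = x$states$duration_s[k],
    target_R = matrix(unlist(x$states$target_R[[k]]), 6, 6, byrow = TRUE,
                      dimnames = list(.rhythms, .rhythms))
  ))
  generator_spec(states,
                 baseline_weights = x$baseline_weights,
                 modulation_depth = x$modulation_depth,
                 envelope_timescale_s = x$envelope_timescale_s,
                 noise_floor = x$noise_floor,
                 sample_rate_hz = x$sample_rate_hz,
                 seed = x$seed)
}
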