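# Statistical-test battery: shuffle surrogate (significance threshold
# calibration), random-subject pairing surrogate (destroys physiological
# coupling), Fourier phase randomization (preserves the amplitude spectrum,
# destroys envelope co-modulation timing), absolute-power control (global
# power trends induce spurious positive coupling), p-value summaries,
# leave-one-out Wilcoxon profile-collapse tests, and time-scale sweeps.

surrogate_report <- function(kind, seed, payload) {
  structure(c(list(kind = kind, seed = seed), payload),
            class = "surrogate_report")
}

#' @export
print.surrogate_report <- function(x, ...) {
  cat(sprintf("<surrogate_report> kind=%s seed=%s\n", x$kind,
              format(x$seed)))
  if (!is.null(x$fraction_within))
    cat(sprintf("  fraction of |C| <= C0: %.4f over %d values\n",
                x$fraction_within, length(x$values)))
  invisible(x)
}

#' Shuffle surrogate
#'
#' Independently permutes each band's smoothed relative-power samples within
#' every annotated session (destroying the temporal alignment that carries
#' coupling while preserving each band's amplitude distribution), then runs
#' the standard coupling pipeline. The fraction of window correlations inside
#' \[-C0, +C0\] calibrates the significance threshold. Optional block
#' shuffling (`block_s`) permutes contiguous blocks instead of single
#' samples, for sensitivity analysis.
#'
#' @param bp A smoothed-relative band-power series with annotations.
#' @param cfg An [analysis_config()].
#' @param seed Mandatory seed.
#' @param block_s Optional block length in seconds (NULL = single samples).
#' @return A `"surrogate_report"` with the shuffled windows, pooled values,
#'   profile and `fraction_within`.
#' @export
shuffle_surrogate <- function(bp, cfg = analysis_config(), seed, block_s = NULL) {
  stopifnot(inherits(bp, "band_power"))
  if (bp$mode != "smoothed_relative")
    stop("shuffle_surrogate expects a smoothed_relative series")
  if (min(bp$annotations$end_s - bp$annotations$start_s) < cfg$corr_window_s)
    stop("a session is shorter than the correlation window")
  shuffled <- bp
  with_seed(seed, {
    for (r in seq_len(nrow(bp$annotations))) {
      ann <- bp$annotations[r, ]
      idx <- which(bp$time_s >= ann$start_s - 1e-9 & bp$time_s < ann$end_s - 1e-9)
      for (b in 1:6) {
        if (is.null(block_s)) {
          shuffled$values[b, idx] <- bp$values[b, sample(idx)]
        } else {
          nb <- length(idx) %/% block_s
          blocks <- split(idx[seq_len(nb * block_s)],
                          rep(seq_len(nb), each = block_s))
          perm <- unlist(blocks[sample(nb)], use.names = FALSE)
          shuffled$values[b, idx[seq_len(nb * block_s)]] <- bp$values[b, perm]
        }
      }
    }
  })
  cw <- coupling_windows(shuffled, cfg, allow_absolute = TRUE)
  vals <- cw$C[cw$valid]
  surrogate_report("shuffle", seed, list(
    windows = cw, values = vals,
    profile = build_profile(vals, cfg, pair = "pooled", state = "shuffled"),
    fraction_within = mean(abs(vals) <= cfg$threshold),
    threshold = cfg$threshold
  ))
}

#' Random-subject pairing surrogate
#'
#' For each realization and each rhythm pair (i, j), band i is taken from one
#' subject and band j from a different, uniformly drawn subject during the
#' same physiological state; windowed correlations are pooled across
#' realizations. Cross-subject amplitude modulations do not synchronize, so
#' the pooled profiles must show D+ ~ D- with no class structure.
#'
#' @param bp_list Named list of smoothed-relative band-power series, one per
#'   subject (>= 2), each annotated with the requested state.
#' @param state State label to pair within.
#' @param n_realizations Number of surrogate pairings (default 19).
#' @param seed Mandatory seed.
#' @param cfg An [analysis_config()].
#' @return A `"surrogate_report"` with per-pair pooled values, D+/-, and the
#'   pairing log (no subject is ever paired with itself).
#' @export
random_pair_surrogate <- function(bp_list, state, n_realizations = 19, seed,
                                  cfg = analysis_config()) {
  if (length(bp_list) < 2) stop("need at least two subjects")
  if (n_realizations < 1) stop("n_realizations must be positive")
  L <- as.integer(cfg$corr_window_s)
  sessions <- lapply(bp_list, function(bp) {
    ann <- bp$annotations[bp$annotations$label == state, , drop = FALSE]
    if (nrow(ann) == 0) stop("state '", state, "' missing for a subject")
    idx <- unlist(lapply(seq_len(nrow(ann)), function(r)
      which(bp$time_s >= ann$start_s[r] - 1e-9 & bp$time_s < ann$end_s[r] - 1e-9)))
    bp$values[, idx, drop = FALSE]
  })
  ns <- length(sessions)
  pairs <- rhythm_pairs()
  values <- stats::setNames(vector("list", nrow(pairs)), pairs$pair)
  log <- list()
  with_seed(seed, {
    for (r in seq_len(n_realizations)) {
      for (k in seq_len(nrow(pairs))) {
        a <- sample.int(ns, 1)
        b <- (seq_len(ns)[-a])[sample.int(ns - 1L, 1)]
        Tn <- min(ncol(sessions[[a]]), ncol(sessions[[b]]))
        nw <- Tn %/% L
        if (nw == 0) next
        for (wdx in seq_len(nw)) {
          cols <- ((wdx - 1L) * L + 1L):(wdx * L)
          xi <- sessions[[a]][pairs$i[k], cols]
          xj <- sessions[[b]][pairs$j[k], cols]
          sdx <- sqrt(mean((xi - mean(xi))^2))
          sdy <- sqrt(mean((xj - mean(xj))^2))
          if (sdx == 0 || sdy == 0) next
          values[[k]] <- c(values[[k]],
                           mean((xi - mean(xi)) * (xj - mean(xj))) / (sdx * sdy))
        }
        log[[length(log) + 1L]] <- data.frame(
          realization = r, pair = pairs$pair[k],
          subject_i = names(bp_list)[a] %||% a,
          subject_j = names(bp_list)[b] %||% b, stringsAsFactors = FALSE)
      }
    }
  })
  D <- t(vapply(values, degree_of_coupling, c(D_plus = 0, D_minus = 0),
                threshold = cfg$threshold))
  surrogate_report("random_pair", seed, list(
    state = state, n_realizations = n_realizations, values = values,
    degree = data.frame(pair = pairs$pair, D, row.names = NULL),
    pairing_log = do.call(rbind, log)
  ))
}

#' Fourier phase randomization
#'
#' Per channel: forward FFT, multiply every positive-frequency bin by an
#' independent unit-modulus random phase, enforce Hermitian symmetry (DC and
#' Nyquist stay real), inverse FFT. The amplitude spectrum — hence the
#' average band powers and linear autocorrelation — is preserved exactly,
#' while the envelope co-modulation timing that carries amplitude-amplitude
#' coupling is destroyed.
#'
#' @param rec An `eeg_recording`.
#' @param seed Mandatory seed.
#' @return The phase-randomized `eeg_recording`.
#' @export
phase_randomize <- function(rec, seed) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$samples)
  half <- (n - 1) %/% 2                 # strictly positive, non-Nyquist bins
  out <- rec
  with_seed(seed, {
    for (ch in seq_len(nrow(rec$samples))) {
      X <- stats::fft(rec$samples[ch, ])
      ph <- exp(2i * pi * stats::runif(half))
      X[2:(half + 1)] <- X[2:(half + 1)] * ph
      X[n:(n - half + 1)] <- Conj(X[2:(half + 1)])
      if (n %% 2 == 0) X[n / 2 + 1] <- abs(X[n / 2 + 1]) * sign(Re(X[n / 2 + 1]))
      out$samples[ch, ] <- Re(stats::fft(X, inverse = TRUE)) / n
    }
  })
  out
}

#' Absolute-power control
#'
#' Runs the coupling pipeline on ABSOLUTE band power (after the same moving
#' average), which is deliberately guarded: global trends in total EEG power
#' drive all bands up and down together and induce spurious positive
#' correlations for every pair, which is exactly what this control
#' demonstrates. `confirm = TRUE` must be set explicitly.
#'
#' @param bp An absolute-mode band-power series with annotations.
#' @param cfg An [analysis_config()].
#' @param confirm Explicit opt-in flag.
#' @return A `"surrogate_report"` with the windows and per-state degree
#'   matrices computed from absolute power.
#' @export
absolute_power_control <- function(bp, cfg = analysis_config(), confirm = FALSE) {
  if (!isTRUE(confirm))
    stop("absolute-power control refused: set confirm = TRUE ",
         "(correlating absolute band power is a deliberate misuse)")
  stopifnot(inherits(bp, "band_power"))
  if (bp$mode != "absolute") stop("expected an absolute-mode series")
  sm <- bp
  sm$values <- t(apply(bp$values, 1, moving_average, width = cfg$smooth_window_s))
  cw <- coupling_windows(sm, cfg, allow_absolute = TRUE)
  states <- unique(cw$state)
  surrogate_report("absolute_power", NA_integer_, list(
    windows = cw,
    degree = lapply(stats::setNames(states, states), function(s)
      degree_matrices(cw, s, threshold = cfg$threshold))
  ))
}

#' Summarize window p-values
#'
#' Fraction of window correlation p-values below / at-or-above `alpha`,
#' pooled and per pair.
#'
#' @param cw A `"coupling_windows"` object.
#' @param alpha Significance level (default 0.05).
#' @return A list with `pooled` (fractions and n) and `per_pair` data.frame.
#' @export
pvalue_summary <- function(cw, alpha = 0.05) {
  d <- as.data.frame(cw)
  p <- d$p[d$valid & is.finite(d$p)]
  if (length(p) == 0) stop("no valid p-values")
  per <- do.call(rbind, lapply(split(d[d$valid, ], d$pair[d$valid]), function(g)
    data.frame(pair = g$pair[1], frac_below = mean(g$p < alpha),
               frac_above = mean(g$p >= alpha), n = nrow(g))))
  rownames(per) <- NULL
  list(pooled = c(frac_below = mean(p < alpha), frac_above = mean(p >= alpha),
                  n = length(p)),
       per_pair = per, alpha = alpha)
}

# Wilcoxon signed-rank with the zero-inclusive (Pratt) convention and a
# normal approximation with continuity correction and tie adjustment. Zeros
# enter the ranking of |d| but their ranks are discarded from the statistic.
wilcoxon_pratt <- function(d) {
  d <- d[is.finite(d)]
  N <- length(d)
  if (N == 0 || all(d == 0)) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  n0 <- sum(d == 0)
  W <- sum(r[d > 0])
  E <- (N * (N + 1) - n0 * (n0 + 1)) / 4
  ties <- table(abs(d[d != 0]))
  V <- (N * (N + 1) * (2 * N + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (V <= 0) return(list(statistic = W, p_value = 1))
  z <- (W - E - sign(W - E) * 0.5) / sqrt(V)
  list(statistic = W, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Leave-one-out profile-collapse test
#'
#' Two-sided Wilcoxon signed-rank test over the paired bin values of a
#' subject's rescaled smoothed profile and the group profile built without
#' that subject; zero differences are handled with the zero-inclusive
#' (Pratt) convention, and an all-zero difference vector passes with p = 1.
#' Passing (p > 0.05) means the subject's coupling profile conforms to the
#' group shape.
#'
#' @param subject_profile,group_profile `"coupling_profile"` objects on
#'   identical bin grids.
#' @param alpha Significance level (default 0.05).
#' @return A list with `statistic`, `p_value`, `pass`.
#' @export
collapse_test <- function(subject_profile, group_profile, alpha = 0.05) {
  stopifnot(inherits(subject_profile, "coupling_profile"),
            inherits(group_profile, "coupling_profile"))
  if (!isTRUE(all.equal(subject_profile$bin_edges, group_profile$bin_edges)))
    stop("profiles are on different bin grids")
  w <- wilcoxon_pratt(subject_profile$profile - group_profile$profile)
  c(w, list(pass = w$p_value > alpha, alpha = alpha))
}

#' Time-scale sweep
#'
#' Reruns smoothing + coupling + degree-of-coupling over a grid of
#' correlation-window and smoothing-window lengths, reporting D+/- per pair
#' and state and the class labels per setting. Settings whose smoothing
#' window exceeds half the correlation window are skipped with a warning
#' (a longer average would leak information across window boundaries), as
#' are windows longer than a session.
#'
#' @param bp A relative-mode (unsmoothed) band-power series with annotations.
#' @param cfg Base [analysis_config()].
#' @param corr_windows,smooth_windows Grids in seconds.
#' @return A list with `table` (setting x state x pair) and `classes`
#'   (class labels per setting, NA where a setting was skipped).
#' @export
timescale_sweep <- function(bp, cfg = analysis_config(),
                            corr_windows = c(20, 30, 45, 60),
                            smooth_windows = c(8, 14, 20)) {
  stopifnot(inherits(bp, "band_power"))
  if (bp$mode != "relative") stop("timescale_sweep expects a relative series")
  rows <- list(); classes <- list()
  for (sw in smooth_windows) for (lw in corr_windows) {
    key <- sprintf("L%d_s%d", lw, sw)
    if (sw > lw / 2) {
      warning("skipping ", key, ": smoothing window exceeds half the ",
              "correlation window")
      classes[[key]] <- NA
      next
    }
    if (lw > max(bp$annotations$end_s - bp$annotations$start_s)) {
      warning("skipping ", key, ": correlation window exceeds every session")
      classes[[key]] <- NA
      next
    }
    cfg_k <- cfg; cfg_k$corr_window_s <- lw; cfg_k$smooth_window_s <- sw
    cw <- coupling_windows(smooth_band_power(bp, sw), cfg_k)
    states <- unique(cw$state)
    dms <- lapply(stats::setNames(states, states), function(s)
      degree_matrices(cw, s, threshold = cfg$threshold))
    cl <- if (length(states) >= 2) classify_pairs(dms)$class else NA
    classes[[key]] <- cl
    pr <- rhythm_pairs()
    for (s in states) {
      d <- dms[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        corr_window_s = lw, smooth_window_s = sw, state = s, pair = pr$pair,
        D_plus = d$D_plus[cbind(pr$i, pr$j)],
        D_minus = d$D_minus[cbind(pr$i, pr$j)], stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), classes = classes)
}

#' Serialize a surrogate report to JSON
#'
#' Writes kind, seed and scalar summaries (not the raw value pools).
#'
#' @param report A `"surrogate_report"`.
#' @param path File path.
#' @export
write_surrogate_report <- function(report, path) {
  keep <- list(kind = report$kind, seed = report$seed)
  if (!is.null(report$fraction_within))
    keep$fraction_within <- report$fraction_within
  if (!is.null(report$threshold)) keep$threshold <- report$threshold
  if (is.data.frame(report$degree)) keep$degree <- report$degree
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
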