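# Window-wise cross-correlation between rhythms: the smoothed relative power
# of each band is z-scored within non-overlapping L-second segments (L = 30 s
# by default) using the population standard deviation, and the 6x6 matrix
# C = (1/L) s s^T is computed per segment. With the divisor-L convention the
# 1/L prefactor yields exactly +/-1 at perfect (anti-)correlation, and C_ij
# equals the Pearson correlation within the window.

#' Analysis configuration
#'
#' Houses the windowing and histogram parameters of the coupling analysis:
#' correlation window length `corr_window_s` (L, default 30 s), significance
#' threshold `threshold` (C0, default 0.5), histogram bin width `hist_bin`
#' (default 0.05, i.e. 40 bins over \[-1, 1\]), profile smoothing width
#' `hist_smooth_bins` (default 5), and spectral/smoothing settings used by
#' the preprocessing stages.
#'
#' @param corr_window_s Correlation window L in seconds (>= 3).
#' @param threshold Significance threshold C0 in (0, 1).
#' @param hist_bin Histogram bin width; must divide the range 2 evenly.
#' @param hist_smooth_bins Moving-average width for profile smoothing.
#' @param smooth_window_s Band-power moving-average window (seconds).
#' @param fft_window_s,fft_step_s Short-time FFT window and hop (seconds).
#' @param seed Optional default seed for stochastic operations.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(corr_window_s = 30, threshold = 0.5,
                            hist_bin = 0.05, hist_smooth_bins = 5,
                            smooth_window_s = 14,
                            fft_window_s = 2, fft_step_s = 1, seed = NULL) {
  stopifnot(corr_window_s >= 3, threshold > 0, threshold < 1,
            hist_smooth_bins >= 1)
  if (abs(2 / hist_bin - round(2 / hist_bin)) > 1e-9)
    stop("hist_bin must divide the correlation range [-1, 1] evenly")
  structure(
    list(corr_window_s = corr_window_s, threshold = threshold,
         hist_bin = hist_bin, hist_smooth_bins = hist_smooth_bins,
         smooth_window_s = smooth_window_s,
         fft_window_s = fft_window_s, fft_step_s = fft_step_s, seed = seed),
    class = "analysis_config"
  )
}

#' Segment a band-power series into per-session correlation windows
#'
#' Per annotated session, consecutive non-overlapping `corr_window_s`-sample
#' segments are taken from the session start (trailing partial segments are
#' discarded: `floor(session_samples / L)` windows); segments never straddle
#' session boundaries. Sessions shorter than L contribute zero windows with
#' a warning.
#'
#' @param bp A band-power series with annotations.
#' @param cfg An [analysis_config()].
#' @return A list of segments, each a list with `state`, `subject_id`,
#'   `test_id`, `window_index`, `start_s` and the sample indices `idx`.
#' @export
segment_windows <- function(bp, cfg = analysis_config()) {
  stopifnot(inherits(bp, "band_power"))
  if (is.null(bp$annotations) || nrow(bp$annotations) == 0)
    stop("band-power series has no session annotations")
  L <- as.integer(cfg$corr_window_s)
  segs <- list()
  for (r in seq_len(nrow(bp$annotations))) {
    ann <- bp$annotations[r, ]
    idx <- which(bp$time_s >= ann$start_s - 1e-9 & bp$time_s < ann$end_s - 1e-9)
    nw <- length(idx) %/% L
    if (nw == 0) {
      warning("session '", ann$label, "' (", length(idx),
              " samples) shorter than the correlation window; skipped")
      next
    }
    for (k in seq_len(nw)) {
      w_idx <- idx[((k - 1L) * L + 1L):(k * L)]
      segs[[length(segs) + 1L]] <- list(
        state = ann$label, subject_id = ann$subject_id, test_id = ann$test_id,
        window_index = k, start_s = bp$time_s[w_idx[1]], idx = w_idx
      )
    }
  }
  segs
}

#' Cross-correlation matrix of one window
#'
#' Each band is z-scored within the window with the population (divisor-L)
#' standard deviation; then `C = (1/L) s s^T`. Bands with zero variance or
#' flagged samples are invalid: their row and column (diagonal included) are
#' NaN and excluded from pooling.
#'
#' @param segment 6 x L numeric matrix (rows in [rhythms()] order).
#' @return 6x6 symmetric matrix with unit diagonal where defined, entries in
#'   \[-1, 1\]; attribute `"valid"` marks usable bands.
#' @export
window_correlation_matrix <- function(segment) {
  segment <- as.matrix(segment)
  L <- ncol(segment)
  stopifnot(nrow(segment) == 6, L >= 3)
  mu <- rowMeans(segment)
  sd_pop <- sqrt(rowMeans((segment - mu)^2))
  valid <- apply(segment, 1, function(r) all(is.finite(r))) & sd_pop > 0
  s <- (segment - mu) / sd_pop
  s[!valid, ] <- 0
  C <- tcrossprod(s) / L
  C <- pmin(pmax(C, -1), 1)
  C[!valid, ] <- NaN
  C[, !valid] <- NaN
  diag(C) <- ifelse(valid, 1, NaN)
  dimnames(C) <- list(.rhythms, .rhythms)
  attr(C, "valid") <- valid
  C
}

#' Two-sided p-value of a window correlation
#'
#' Tests `C` against zero with `t = C sqrt((L-2)/(1-C^2))` on L-2 degrees of
#' freedom; `p(+/-1) = 0` by convention. Vectorized over `C`.
#'
#' @param C Correlation value(s) in \[-1, 1\].
#' @param L Window length (>= 3).
#' @return p-value(s); NaN inputs propagate.
#' @export
correlation_pvalue <- function(C, L) {
  stopifnot(L >= 3)
  p <- rep(NaN, length(C))
  ok <- is.finite(C)
  if (any(abs(C[ok]) > 1 + 1e-12)) stop("|C| must not exceed 1")
  Cok <- pmin(pmax(C[ok], -1), 1)
  lim <- abs(Cok) >= 1 - 1e-15
  tt <- Cok * sqrt((L - 2) / pmax(1 - Cok^2, .Machine$double.xmin))
  pv <- 2 * stats::pt(-abs(tt), df = L - 2)
  pv[lim] <- 0
  p[ok] <- pv
  p
}

#' Compute coupling windows for a whole series
#'
#' Applies [segment_windows()] and [window_correlation_matrix()] across all
#' annotated sessions and returns the window-wise correlations of all 15
#' rhythm pairs in long format, with p-values from [correlation_pvalue()].
#' Requires a smoothed-relative series; set `allow_absolute = TRUE` only for
#' the absolute-power control (see [absolute_power_control()]).
#'
#' @param bp A band-power series (smoothed-relative mode).
#' @param cfg An [analysis_config()].
#' @param allow_absolute Explicit override admitting non-smoothed-relative
#'   input (absolute-power control).
#' @return An object of class `"coupling_windows"`: a data.frame with columns
#'   `subject_id, test_id, channel, state, window_index, start_s, i, j, pair,
#'   C, p, valid` and the config as attribute `"config"`.
#' @export
coupling_windows <- function(bp, cfg = analysis_config(), allow_absolute = FALSE) {
  stopifnot(inherits(bp, "band_power"))
  if (bp$mode != "smoothed_relative" && !allow_absolute)
    stop("coupling_windows expects a smoothed_relative series; ",
         "set allow_absolute = TRUE only for the absolute-power control")
  segs <- segment_windows(bp, cfg)
  pairs <- rhythm_pairs()
  L <- as.integer(cfg$corr_window_s)
  rows <- lapply(segs, function(sg) {
    C <- window_correlation_matrix(bp$values[, sg$idx, drop = FALSE])
    cij <- C[cbind(pairs$i, pairs$j)]
    data.frame(
      subject_id = sg$subject_id, test_id = sg$test_id, channel = bp$channel,
      state = sg$state, window_index = sg$window_index, start_s = sg$start_s,
      i = pairs$i, j = pairs$j, pair = pairs$pair,
      C = cij, p = correlation_pvalue(cij, L), valid = is.finite(cij),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  attr(out, "config") <- cfg
  class(out) <- c("coupling_windows", "data.frame")
  out
}

#' Write coupling windows as long-format CSV
#'
#' @param cw A `"coupling_windows"` object.
#' @param path File path.
#' @export
write_coupling_windows <- function(cw, path) {
  utils::write.csv(as.data.frame(cw), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# rbind coupling windows from several subjects/channels, keeping the config.
bind_coupling_windows <- function(cw_list) {
  cfg <- attr(cw_list[[1]], "config")
  out <- do.call(rbind, lapply(cw_list, as.data.frame))
  attr(out, "config") <- cfg
  class(out) <- c("coupling_windows", "data.frame")
  out
}
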