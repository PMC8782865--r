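# The central fit: from band power (or a recording) to coupling windows,
# per-state profiles and degree matrices, dual networks, and the three-class
# assignment.

#' Fit a synchronous amplitude network analysis
#'
#' The estimator at the package's core: window-wise cross-correlation of
#' smoothed relative band power, summarized per physiological state by
#' coupling distribution profiles, degree-of-coupling matrices
#' `D+ = P(C > C0)` / `D- = P(C < -C0)`, and dual positive/anti-correlated
#' rhythm networks. When at least two states are annotated, every rhythm
#' pair is classified as `anti`, `positive` or `mixed` by strict dominance
#' of D- or D+ across all states.
#'
#' @param x One of: a smoothed-relative [band_power()] series; a
#'   relative-mode series (smoothed internally with
#'   `config$smooth_window_s`); an annotated `eeg_recording` (spectral
#'   decomposition of `channel` is run first); or a list of band-power
#'   series from several subjects/tests, whose windows are pooled as in
#'   group-level analyses.
#' @param config An [analysis_config()].
#' @param channel Channel to analyze when `x` is a recording.
#' @param ... Unused.
#' @return An object of class `"sana"` with components `windows`
#'   (`coupling_windows`), `profiles` (per state, per pair), `degree`
#'   (per-state `degree_matrices`), `networks` (per state, positive/anti),
#'   `classes` (pair classification, NULL with a single state), `states`,
#'   and `config`.
#' @seealso [summary.sana()], [coef.sana()], [plot.sana()]
#' @export
sana <- function(x, config = analysis_config(), channel = NULL, ...) {
  if (inherits(x, "eeg_recording")) {
    bp <- band_power_series(x, channel = channel %||% x$channel_labels[1],
                            fft_window_s = config$fft_window_s,
                            fft_step_s = config$fft_step_s)
    x <- smooth_band_power(to_relative(bp), config$smooth_window_s)
  }
  if (inherits(x, "band_power")) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "band_power")))
  x <- lapply(x, function(bp) {
    if (bp$mode == "relative") smooth_band_power(bp, config$smooth_window_s)
    else bp
  })
  cw <- bind_coupling_windows(lapply(x, coupling_windows, cfg = config))
  states <- unique(cw$state)
  pairs <- rhythm_pairs()
  degree <- lapply(stats::setNames(states, states), function(s)
    degree_matrices(cw, s, threshold = config$threshold))
  profiles <- lapply(stats::setNames(states, states), function(s) {
    pl <- lapply(seq_len(nrow(pairs)), function(k)
      build_profile(pool_values(cw, c(pairs$i[k], pairs$j[k]), state = s),
                    config, pair = pairs$pair[k], state = s))
    stats::setNames(pl, pairs$pair)
  })
  networks <- lapply(degree, function(d)
    list(positive = build_network(d, "positive"),
         anti = build_network(d, "anti")))
  classes <- if (length(states) >= 2) classify_pairs(degree) else NULL
  structure(
    list(windows = cw, profiles = profiles, degree = degree,
         networks = networks, classes = classes, states = states,
         config = config),
    class = "sana"
  )
}

#' @export
print.sana <- function(x, ...) {
  cat("Synchronous amplitude network analysis\n")
  cat(sprintf("  %d window(s) x 15 pairs over %d state(s): %s\n",
              nrow(x$windows) / 15, length(x$states),
              paste(x$states, collapse = ", ")))
  cat(sprintf("  L = %g s, C0 = %g\n",
              x$config$corr_window_s, x$config$threshold))
  if (!is.null(x$classes)) {
    tab <- table(x$classes$class)
    cat("  classes:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a fitted analysis
#'
#' @param object A `"sana"` fit.
#' @param ... Unused.
#' @return A data.frame with one row per pair and state: D+, D-, n and (when
#'   available) the coupling class.
#' @export
summary.sana <- function(object, ...) {
  pr <- rhythm_pairs()
  rows <- do.call(rbind, lapply(names(object$degree), function(s) {
    d <- object$degree[[s]]
    data.frame(state = s, pair = pr$pair,
               D_plus = d$D_plus[cbind(pr$i, pr$j)],
               D_minus = d$D_minus[cbind(pr$i, pr$j)],
               n = d$n[cbind(pr$i, pr$j)], stringsAsFactors = FALSE)
  }))
  if (!is.null(object$classes))
    rows$class <- object$classes$class[match(rows$pair, object$classes$pair)]
  class(rows) <- c("summary.sana", "data.frame")
  rows
}

#' Extract the degree-of-coupling matrices
#'
#' @param object A `"sana"` fit.
#' @param ... Unused.
#' @return Named list per state, each with 6x6 `D_plus` and `D_minus`.
#' @export
coef.sana <- function(object, ...) {
  lapply(object$degree, function(d) list(D_plus = d$D_plus, D_minus = d$D_minus))
}

#' Plot coupling profiles
#'
#' Draws the rescaled smoothed coupling profile for each requested pair and
#' state on a base-graphics grid, with the +/-C0 thresholds marked.
#'
#' @param x A `"sana"` fit.
#' @param pairs Pair labels to draw (default: the first 6).
#' @param states States to overlay (default: all).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sana <- function(x, pairs = NULL, states = NULL, ...) {
  states <- states %||% x$states
  pairs <- pairs %||% utils::head(rhythm_pairs()$pair, 6)
  old <- graphics::par(mfrow = c(ceiling(length(pairs) / 3), min(3, length(pairs))),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(max(2L, length(states)), "Dark 3")
  for (p in pairs) {
    first <- TRUE
    for (s_i in seq_along(states)) {
      pf <- x$profiles[[states[s_i]]][[p]]
      if (is.null(pf)) next
      if (first) {
        graphics::plot(pf$bin_centers, pf$profile, type = "l", col = cols[s_i],
                       xlab = "C", ylab = "profile", main = p,
                       xlim = c(-1, 1), ylim = c(0, 1.05), ...)
        graphics::abline(v = c(-1, 1) * x$config$threshold, lty = 3)
        first <- FALSE
      } else {
        graphics::lines(pf$bin_centers, pf$profile, col = cols[s_i])
      }
    }
    if (p == pairs[1])
      graphics::legend("topleft", legend = states, col = cols[seq_along(states)],
                       lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}
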