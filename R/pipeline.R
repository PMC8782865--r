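# End-to-end pipeline: preprocess -> band power -> relative -> smooth ->
# coupling -> profiles -> degree -> networks, writing every intermediate in
# the package's plain-text formats plus a JSON manifest.

#' Run the full analysis pipeline on a recording
#'
#' Executes the standard chain per analyzed channel and writes every
#' intermediate artifact under `out_dir`: band-power CSVs (absolute and
#' smoothed relative), the long-format coupling-window CSV, per-pair/state
#' profile CSVs, degree-matrix JSONs, network edge-list CSVs, and a
#' `manifest.json` recording the configuration, seeds and row counts.
#'
#' @param rec An annotated `eeg_recording` (or a path readable by
#'   [read_recording()]).
#' @param out_dir Output directory (created if missing).
#' @param cfg An [analysis_config()].
#' @param channels Channels to analyze (default: all).
#' @param highpass_hz High-pass cutoff applied first (NULL to skip).
#' @param laplacian Adjacency list for [surface_laplacian()] (NULL to skip;
#'   skipped automatically for single-channel recordings).
#' @param annotations_path Sidecar annotation CSV when `rec` is a path.
#' @param verbose Log stage progress to standard error.
#' @return Invisibly, a list with the fitted [sana()] objects per channel and
#'   the manifest.
#' @export
run_pipeline <- function(rec, out_dir, cfg = analysis_config(),
                         channels = NULL, highpass_hz = 0.1,
                         laplacian = NULL, annotations_path = NULL,
                         verbose = FALSE) {
  log <- function(...) if (verbose) message("[sana] ", ...)
  if (is.character(rec))
    rec <- read_recording(rec, annotations_path = annotations_path)
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(rec$annotations) || nrow(rec$annotations) == 0)
    stop("pipeline aborted at stage 'annotations': no session annotations")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  channels <- channels %||% rec$channel_labels

  if (!is.null(highpass_hz)) {
    log("high-pass filter at ", highpass_hz, " Hz")
    rec <- highpass_filter(rec, highpass_hz)
  }
  if (!is.null(laplacian) && length(rec$channel_labels) > 1) {
    log("surface Laplacian")
    rec <- surface_laplacian(rec, laplacian)
  }

  fits <- list()
  counts <- list()
  for (ch in channels) {
    log("channel ", ch, ": spectral decomposition")
    bp_abs <- band_power_series(rec, channel = ch,
                                fft_window_s = cfg$fft_window_s,
                                fft_step_s = cfg$fft_step_s)
    bp_sm <- smooth_band_power(to_relative(bp_abs), cfg$smooth_window_s)
    write_band_power(bp_abs, file.path(out_dir, paste0("bandpower_abs_", ch, ".csv")))
    write_band_power(bp_sm, file.path(out_dir, paste0("bandpower_smooth_", ch, ".csv")))
    log("channel ", ch, ": coupling + profiles + networks")
    fit <- sana(bp_sm, cfg)
    write_coupling_windows(fit$windows,
                           file.path(out_dir, paste0("coupling_", ch, ".csv")))
    for (s in names(fit$degree)) {
      write_degree_matrices(fit$degree[[s]],
        file.path(out_dir, sprintf("degree_%s_%s.json", ch, s)))
      for (pol in c("positive", "anti"))
        export_network(fit$networks[[s]][[pol]],
          file.path(out_dir, sprintf("network_%s_%s_%s.csv", ch, s, pol)))
      for (pr in names(fit$profiles[[s]]))
        write_profile(fit$profiles[[s]][[pr]],
          file.path(out_dir, sprintf("profile_%s_%s_%s.csv", ch, s, pr)))
    }
    fits[[ch]] <- fit
    counts[[ch]] <- list(windows = nrow(fit$windows) / 15,
                         states = length(fit$degree))
  }
  manifest <- list(
    package = "sana",
    version = as.character(utils::packageVersion("sana")),
    config = unclass(cfg), channels = channels,
    sample_rate_hz = rec$sample_rate_hz,
    n_samples = ncol(rec$samples), counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log("done: ", out_dir)
  invisible(list(fits = fits, manifest = manifest, out_dir = out_dir))
}
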