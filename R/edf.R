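# Minimal European Data Format (EDF) writer/reader: plain EDF, 16-bit
# little-endian samples, one data record per second, one signal per channel.
# Annotations travel in the sidecar CSV (see read_annotations), not EDF+ TALs.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Samples are quantized to 16 bits over the per-channel physical range, the
#' standard EDF precision; round-trips agree within one quantization step.
#' The sampling rate must be an integer (one data record per second); a
#' trailing partial second is dropped.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sample_rate_hz
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sample rate (1 s data records)")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n_rec <- ncol(rec$samples) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  gain <- (dmax - dmin) / (pmax_ - pmin_)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4)
  )
  sig <- paste0(
    paste(edf_pad(rec$channel_labels, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(sprintf("%.6g", pmin_), 8), collapse = ""),
    paste(edf_pad(sprintf("%.6g", pmax_), 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  dig <- round((x - pmin_) * gain + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  # interleave: per record, all samples of signal 1, then signal 2, ...
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads plain 16-bit EDF files with equal record durations (as written by
#' [write_edf()] and most acquisition systems).
#'
#' @param path EDF file path.
#' @return An `eeg_recording` (annotations NULL; see [read_annotations()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- num(8); rd(44)
  n_rec <- num(8); rec_dur <- num(8); ns <- as.integer(num(4))
  if (!is.finite(ns) || ns < 1)
    stop("malformed EDF header in ", path, " (byte offset 252: signal count)")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  if (anyDuplicated(labels)) stop("duplicate channel labels in ", path)
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # dimension
  pmin_ <- vapply(seq_len(ns), function(i) num(8), 0)
  pmax_ <- vapply(seq_len(ns), function(i) num(8), 0)
  dmin <- vapply(seq_len(ns), function(i) num(8), 0)
  dmax <- vapply(seq_len(ns), function(i) num(8), 0)
  for (i in seq_len(ns)) rd(80)            # prefilter
  spr <- vapply(seq_len(ns), function(i) num(8), 0)
  seek(con, hdr_bytes)
  total <- sum(spr) * n_rec
  raw16 <- readBin(con, "integer", n = total, size = 2L,
                   signed = TRUE, endian = "little")
  if (length(raw16) < total) stop("truncated EDF data in ", path)
  out <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  offs <- c(0, cumsum(spr))
  per_rec <- sum(spr)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer((offs[i] + 1):(offs[i] + spr[i]),
                           (seq_len(n_rec) - 1L) * per_rec, `+`))
    gain <- (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
    out[i, ] <- (raw16[idx] - dmin[i]) * gain + pmin_[i]
  }
  recording(out, spr[1] / rec_dur, channel_labels = labels)
}
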