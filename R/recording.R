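# Recording and annotation containers plus CSV I/O. EDF I/O lives in edf.R.

#' Construct a multi-channel EEG recording
#'
#' @param samples Numeric matrix, channels x time (microvolts).
#' @param sample_rate_hz Sampling rate in Hz (positive).
#' @param channel_labels Unique channel names (10--20 montage names for real
#'   data); defaults to the rownames of `samples`.
#' @param annotations Optional session-annotation data.frame as returned by
#'   [session_annotations()].
#' @return An object of class `"eeg_recording"`.
#' @export
recording <- function(samples, sample_rate_hz, channel_labels = rownames(samples),
                      annotations = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  stopifnot(is.numeric(samples), length(sample_rate_hz) == 1L, sample_rate_hz > 0)
  if (!all(is.finite(samples))) stop("recording samples must be finite")
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (length(channel_labels) != nrow(samples))
    stop("channel_labels length must match the number of rows of samples")
  rownames(samples) <- channel_labels
  dur <- ncol(samples) / sample_rate_hz
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
    if (any(annotations$end_s > dur + 1e-9))
      stop("annotations extend past the recording duration")
  }
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         channel_labels = channel_labels, annotations = annotations),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate_hz,
              ncol(x$samples) / x$sample_rate_hz))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$annotations))
    cat(sprintf("  sessions: %d (%s)\n", nrow(x$annotations),
                paste(x$annotations$label, collapse = ", ")))
  invisible(x)
}

#' Build a session-annotation table
#'
#' Sessions are half-open intervals `[start_s, end_s)` in seconds from the
#' recording start, tagged with a physiological-state label, subject and test
#' identifiers (the test id distinguishes protocol repetitions).
#'
#' @param label Character vector of state labels.
#' @param start_s,end_s Numeric session boundaries in seconds.
#' @param subject_id,test_id Identifiers, recycled to the number of sessions.
#' @return A validated, time-ordered data.frame.
#' @export
session_annotations <- function(label, start_s, end_s,
                                subject_id = "S01", test_id = "T1") {
  ann <- data.frame(subject_id = subject_id, test_id = test_id,
                    label = label, start_s = start_s, end_s = end_s,
                    stringsAsFactors = FALSE)
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  req <- c("subject_id", "test_id", "label", "start_s", "end_s")
  if (!all(req %in% names(ann)))
    stop("annotations need columns: ", paste(req, collapse = ", "))
  bad <- which(!(ann$start_s >= 0 & ann$start_s < ann$end_s))
  if (length(bad))
    stop("invalid annotation interval at row ", bad[1],
         " (need 0 <= start_s < end_s)")
  ann <- ann[order(ann$start_s), , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann) > 1) {
    ov <- which(ann$start_s[-1] < ann$end_s[-nrow(ann)] - 1e-9)
    if (length(ov)) stop("overlapping annotations at row ", ov[1] + 1)
  }
  ann
}

#' Read a session-annotation CSV
#'
#' Expects columns `subject_id,test_id,label,start_s,end_s`.
#'
#' @param path File path.
#' @return Annotation data.frame (empty with a warning if the file has no rows).
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(ann) == 0) {
    warning("empty annotation file: ", path)
    return(ann)
  }
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param ann Annotation data.frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write recordings as CSV
#'
#' The CSV layout is one column per channel with a header row of channel
#' labels, one sample per row, preceded by `#`-prefixed metadata lines
#' (sample rate). `format` is inferred from the file extension when missing.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`.
#' @param annotations_path Optional sidecar annotation CSV.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           annotations_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  rec <- switch(format, csv = read_recording_csv(path), edf = read_edf(path))
  if (!is.null(annotations_path))
    rec$annotations <- read_annotations(annotations_path)
  rec
}

read_recording_csv <- function(path) {
  lines <- readLines(path, n = 20L)
  meta <- grep("^#", lines, value = TRUE)
  rate <- NA_real_
  m <- grep("sample_rate_hz", meta, value = TRUE)
  if (length(m)) rate <- as.numeric(sub(".*sample_rate_hz[:= ]+", "", m[1]))
  if (!is.finite(rate))
    stop("malformed header in ", path, ": missing '# sample_rate_hz:' line")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (anyDuplicated(names(df))) stop("duplicate channel labels in ", path)
  recording(t(as.matrix(df)), rate, channel_labels = names(df))
}

#' @rdname read_recording
#' @param rec An `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %.10g", rec$sample_rate_hz), con)
  utils::write.table(t(rec$samples), con, sep = ",", row.names = FALSE,
                     col.names = rec$channel_labels, quote = FALSE)
  invisible(path)
}
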