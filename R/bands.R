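# Rhythm naming and band definitions. The fixed ordering
# delta, theta, alpha, sigma, beta, gamma is used everywhere in the package:
# in band-power matrices, correlation matrices, D+/D- matrices and exported
# edge lists.

.rhythms <- c("delta", "theta", "alpha", "sigma", "beta", "gamma")

#' Rhythm names in canonical order
#'
#' Returns the six rhythm names in the fixed order used throughout the
#' package: delta, theta, alpha, sigma, beta, gamma.
#'
#' @return Character vector of length 6.
#' @export
rhythms <- function() .rhythms

#' Default frequency-band definitions
#'
#' The six physiologically standard EEG bands analyzed by the pipeline:
#' delta 0.5--3.5 Hz, theta 4--7.5 Hz, alpha 8--11.5 Hz, sigma 12--15.5 Hz,
#' beta 16--19.5 Hz, gamma 20--24.5 Hz. Gaps between bands (e.g. 3.5--4 Hz)
#' belong to no band; band edges are inclusive at both ends when summing
#' periodogram bins.
#'
#' @return A data.frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
band_definitions <- function() {
  data.frame(
    name = .rhythms,
    f_lo = c(0.5, 4, 8, 12, 16, 20),
    f_hi = c(3.5, 7.5, 11.5, 15.5, 19.5, 24.5),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands),
            all(c("name", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo <= 0) || any(bands$f_hi <= bands$f_lo))
    stop("band definitions must satisfy 0 < f_lo < f_hi")
  bands
}

#' The 15 unordered rhythm pairs
#'
#' @return A data.frame with columns `i`, `j` (indices into [rhythms()],
#'   i < j) and `pair` (label such as `"delta-gamma"`).
#' @export
rhythm_pairs <- function() {
  idx <- which(upper.tri(diag(6)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    i = idx[, 1], j = idx[, 2],
    pair = paste(.rhythms[idx[, 1]], .rhythms[idx[, 2]], sep = "-"),
    stringsAsFactors = FALSE
  )
}

# Resolve a pair given as "delta-gamma", c("delta","gamma") or c(1,6).
resolve_pair <- function(pair) {
  if (is.character(pair) && length(pair) == 1L)
    pair <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (is.character(pair)) {
    idx <- match(pair, .rhythms)
    if (anyNA(idx)) stop("unknown rhythm name in pair: ", paste(pair, collapse = "-"))
  } else idx <- as.integer(pair)
  stopifnot(length(idx) == 2L, all(idx %in% 1:6), idx[1] != idx[2])
  sort(idx)
}
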