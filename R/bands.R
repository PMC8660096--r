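#' Canonical EEG frequency bands
#'
#' The six oscillation bands used throughout the package, in ascending
#' frequency order: delta (2-4 Hz), theta (4-8 Hz), alpha (8-13 Hz),
#' beta (14-30 Hz), low-gamma (30-55 Hz) and high-gamma (65-80 Hz).
#'
#' @return data.frame with columns \code{name}, \code{low_hz},
#'   \code{high_hz}, one row per band.
#' @examples
#' bandDefinitions()
#' @export
bandDefinitions <- function() {
  data.frame(
    name    = c("delta", "theta", "alpha", "beta", "low-gamma", "high-gamma"),
    low_hz  = c(2, 4, 8, 14, 30, 65),
    high_hz = c(4, 8, 13, 30, 55, 80),
    stringsAsFactors = FALSE
  )
}

# resolve a band given as name, list or one-row data.frame
resolveBand <- function(band) {
  if (is.character(band)) {
    defs <- bandDefinitions()
    i <- match(band, defs$name)
    if (is.na(i)) stop(sprintf("unknown band '%s'", band))
    return(defs[i, , drop = FALSE])
  }
  band <- as.list(band)
  if (is.null(band$low_hz) || is.null(band$high_hz))
    stop("a band needs 'low_hz' and 'high_hz'")
  if (!(band$low_hz > 0 && band$low_hz < band$high_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  data.frame(name = if (is.null(band$name)) "custom" else band$name,
             low_hz = band$low_hz, high_hz = band$high_hz,
             stringsAsFactors = FALSE)
}

#' FIR filter order from the three-cycles rule
#'
#' The filter order is the number of samples spanning \code{cycles} full
#' cycles of the band's lower edge, rounded up:
#' \code{ceiling(cycles * fs / low_hz)}. At fs = 250 Hz this yields orders
#' 375, 188, 94, 54, 25 and 12 for the six canonical bands, and 1500 for a
#' 0.5 Hz broadband edge.
#'
#' @param low_hz lower band edge in Hz (> 0); vectorised.
#' @param fs sampling rate in Hz (> 0).
#' @param cycles number of cycles of the lower edge the filter must span
#'   (default 3).
#' @return integer filter order(s) in samples.
#' @examples
#' firOrder(bandDefinitions()$low_hz, fs = 250)
#' @export
firOrder <- function(low_hz, fs, cycles = 3) {
  if (!is.numeric(low_hz) || any(!is.finite(low_hz)) || any(low_hz <= 0))
    stop("'low_hz' must be positive")
  stopifnotScalar(fs, "fs")
  stopifnotScalar(cycles, "cycles")
  as.integer(ceiling(cycles * fs / low_hz))
}

#' Zero-phase Hamming-window FIR band-pass filter
#'
#' Band-pass filters a series with a Hamming-window FIR filter whose order
#' follows the three-cycles rule ([firOrder]), applied forward and backward
#' (zero phase). The transition bands are anchored at the pass-band edges
#' and extend outward, so the nominal pass band keeps gain ~1 even at the
#' short orders the rule yields for high-frequency bands.
#'
#' @param x numeric series.
#' @param band a band name (see [bandDefinitions]) or a list/one-row
#'   data.frame with \code{low_hz} and \code{high_hz}.
#' @param fs sampling rate in Hz.
#' @param cycles cycles of the lower edge defining the order (default 3).
#' @return filtered series of the same length as \code{x}.
#' @examples
#' fs <- 250; t <- seq(0, 4, by = 1 / fs)
#' y <- bandpassFilter(cos(2 * pi * 10 * t), "alpha", fs)
#' @export
bandpassFilter <- function(x, band, fs, cycles = 3) {
  band <- resolveBand(band)
  stopifnotScalar(fs, "fs")
  ord <- firOrder(band$low_hz, fs, cycles)
  if (length(x) <= 3L * ord)
    stop(sprintf(
      "series too short: %d samples but the order-%d filter needs more than %d",
      length(x), ord, 3L * ord))
  nyq <- fs / 2
  # Hamming main-lobe transition width ~= 3.3 / order (cycles/sample);
  # -6 dB cutoffs placed half a transition width outside the pass band.
  tw <- 3.3 * fs / ord
  lo <- max(band$low_hz - tw / 2, 1e-3)
  hi <- min(band$high_hz + tw / 2, nyq * (1 - 1e-6))
  if (lo >= hi) stop("degenerate pass band after transition-width padding")
  b <- signal::fir1(ord, c(lo, hi) / nyq, type = "pass")
  as.numeric(signal::filtfilt(filt = b, x = x))
}
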