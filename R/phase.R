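#' @include AllClasses.R
NULL

# FFT-based analytic signal: positive frequencies doubled, negative zeroed.
analyticSignal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal of \code{x} by the FFT method and returns
#' the instantaneous phase: the four-quadrant arctangent of the Hilbert
#' transform over the signal itself, wrapped to [-pi, pi], together with
#' its unwrapped (continuous) version.
#'
#' @param x real, finite, non-constant series of length >= 4.
#' @param fs sampling rate in Hz.
#' @return a [PhaseSeries-class].
#' @examples
#' fs <- 250; t <- 0:(4 * fs - 1) / fs
#' ph <- analyticPhase(cos(2 * pi * 10 * t), fs)
#' @export
analyticPhase <- function(x, fs) {
  stopifnotScalar(fs, "fs")
  if (length(x) < 4L) stop("'x' must have at least 4 samples")
  if (any(!is.finite(x))) stop("'x' must be finite")
  if (max(x) == min(x))
    stop("degenerate signal: constant input has no defined phase")
  a <- analyticSignal(x)
  wrapped <- atan2(Im(a), Re(a))
  methods::new("PhaseSeries", wrapped = wrapped,
               unwrapped = unwrapPhase(wrapped), fs = fs)
}

#' Unwrap a wrapped phase sequence
#'
#' Adds multiples of +/- 2*pi wherever consecutive wrapped phases jump by
#' pi or more, producing a continuous phase trajectory. Each output value
#' differs from its input by an integer multiple of 2*pi.
#'
#' @param wrapped phase values in radians (typically in [-pi, pi]).
#' @return unwrapped phase values, same length.
#' @examples
#' unwrapPhase(c(0, pi - 0.1, -pi + 0.1))
#' @export
unwrapPhase <- function(wrapped) {
  as.numeric(signal::unwrap(wrapped))
}

#' Time-varying phase synchrony of one ROI pair
#'
#' The TV-PS series: the first difference (rate of change, radians per
#' sample) of the unwrapped phase difference between two signals. A fixed
#' phase relationship gives values ~0; random relative phase gives
#' noise-like values. \code{trim} samples are dropped from each end of the
#' phase difference before differencing to suppress filter and Hilbert
#' edge artifacts.
#'
#' @param phaseA,phaseB [PhaseSeries-class] objects of equal length and fs.
#' @param roiA,roiB ROI indices stored with the result (roiA < roiB by
#'   convention; indices are metadata and do not reorder the inputs).
#' @param trim samples discarded at each end (default 0).
#' @return a [TVPSSeries-class].
#' @export
tvps <- function(phaseA, phaseB, roiA = 1L, roiB = 2L, trim = 0L) {
  if (length(phaseA@wrapped) != length(phaseB@wrapped))
    stop("phase series lengths differ")
  if (phaseA@fs != phaseB@fs) stop("sampling rates differ")
  d <- phaseA@unwrapped - phaseB@unwrapped
  tvpsFromPhaseDiff(d, phaseA@fs, roiA, roiB, trim)
}

tvpsFromPhaseDiff <- function(d, fs, roiA, roiB, trim = 0L) {
  trim <- as.integer(trim)
  if (trim > 0L) {
    if (length(d) <= 2L * trim + 1L)
      stop("series too short for the requested edge trim")
    d <- d[(trim + 1L):(length(d) - trim)]
  }
  methods::new("TVPSSeries", roiA = as.integer(roiA), roiB = as.integer(roiB),
               values = diff(d), initialPhaseDiff = d[1L], fs = fs)
}

#' TV-PS series for all ROI pairs of a dataset
#'
#' Band-pass filters every ROI series, extracts phases once per ROI, and
#' returns the TV-PS series of every unordered ROI pair (a < b): C(n, 2)
#' series per subject (3486 for the canonical 84-ROI parcellation).
#'
#' @param x a [SourceDataset-class], or a single ROIs x time numeric
#'   matrix.
#' @param band band name or definition (see [bandDefinitions]); use
#'   \code{NULL} to skip filtering (signals already band-limited).
#' @param fs sampling rate, required when \code{x} is a matrix.
#' @param trim edge samples dropped per end; \code{"auto"} (default) uses
#'   the FIR order of the band, or 0 when \code{band} is NULL.
#' @return for a matrix: a list of [TVPSSeries-class] named "a-b"; for a
#'   SourceDataset: a list of such lists, one per subject.
#' @examples
#' m <- matrix(rnorm(5 * 2000), 5)
#' length(allPairsTVPS(m, band = NULL, fs = 250))  # 10
#' @export
allPairsTVPS <- function(x, band = NULL, fs = NULL, trim = "auto") {
  if (methods::is(x, "SourceDataset")) {
    out <- lapply(x@signals, allPairsTVPS, band = band, fs = x@fs,
                  trim = trim)
    names(out) <- x@subjects$id
    return(out)
  }
  if (!is.matrix(x)) stop("'x' must be a matrix or SourceDataset")
  if (is.null(fs)) stop("'fs' is required for matrix input")
  if (nrow(x) < 2L) stop("at least 2 ROIs are required")
  if (identical(trim, "auto")) {
    trim <- if (is.null(band)) 0L
            else firOrder(resolveBand(band)$low_hz, fs)
  }
  unwrapped <- t(apply(x, 1L, function(row) {
    if (!is.null(band)) row <- bandpassFilter(row, band, fs)
    analyticPhase(row, fs)@unwrapped
  }))
  pairs <- roiPairs(nrow(x))
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1L]; b <- pairs[k, 2L]
    out[[k]] <- tvpsFromPhaseDiff(unwrapped[a, ] - unwrapped[b, ], fs,
                                  a, b, trim)
  }
  names(out) <- pairLabels(pairs)
  out
}
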