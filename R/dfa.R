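#' @include AllClasses.R
NULL

#' Signal profile (mean-removed cumulative sum)
#'
#' The object DFA windows and detrends: the cumulative sum of the series
#' after removing its mean. The final element is always 0.
#'
#' @param x numeric series of length >= 2.
#' @return profile series of the same length.
#' @examples
#' signalProfile(c(1, -1, 1, -1))  # 1 0 1 0
#' @export
signalProfile <- function(x) {
  if (length(x) < 2L) stop("'x' must have at least 2 samples")
  cumsum(x - mean(x))
}

#' Log-spaced DFA window lengths
#'
#' \code{nTau} window lengths equidistant on a log scale between
#' \code{minS} and \code{maxS} seconds, converted to integer sample counts
#' (rounded), deduplicated, each at least 4 samples.
#'
#' @param minS,maxS smallest and largest window length in seconds
#'   (0 < minS < maxS).
#' @param nTau number of window lengths (>= 6).
#' @param fs sampling rate in Hz.
#' @param n optional series length in samples; when given, \code{maxS}
#'   windows must fit at least twice (maxS * fs <= n / 2) or an error is
#'   raised.
#' @return integer vector of window lengths in samples, ascending.
#' @examples
#' range(windowLengths(1, 15, 15, 250))  # 250 3750
#' @export
windowLengths <- function(minS, maxS, nTau = 15L, fs = 250, n = NULL) {
  stopifnotScalar(minS, "minS"); stopifnotScalar(maxS, "maxS")
  stopifnotScalar(fs, "fs")
  if (minS >= maxS) stop("'minS' must be smaller than 'maxS'")
  if (nTau < 6L) stop("'nTau' must be at least 6 for a well-posed fit")
  if (!is.null(n) && maxS * fs > n / 2)
    stop(sprintf(
      "largest window (%g s = %d samples) must fit at least twice in %d samples",
      maxS, as.integer(round(maxS * fs)), as.integer(n)))
  taus <- unique(as.integer(round(10^seq(log10(minS), log10(maxS),
                                         length.out = nTau) * fs)))
  taus <- taus[taus >= 4L]
  if (length(taus) < 6L)
    stop("fewer than 6 distinct window lengths; widen the range or raise fs")
  taus
}

#' Fluctuation function for one window length
#'
#' Divides the profile into windows of \code{tau} samples overlapping by
#' \code{overlap} (window k starts at sample floor(k * tau * (1 - overlap)),
#' k = 0, 1, ...; a trailing partial window is dropped), removes the
#' least-squares linear trend from each window, and returns the mean of
#' the per-window standard deviations (population convention, divisor
#' tau).
#'
#' @param profile the signal profile (see [signalProfile]).
#' @param tau window length in samples (at least 2 windows must fit).
#' @param overlap fractional overlap between consecutive windows in
#'   [0, 1), default 0.5.
#' @return F(tau), a non-negative scalar.
#' @export
fluctuationFunction <- function(profile, tau, overlap = 0.5) {
  tau <- as.integer(tau)
  n <- length(profile)
  if (overlap < 0 || overlap >= 1) stop("'overlap' must lie in [0, 1)")
  step <- tau * (1 - overlap)
  k <- 0:floor(n / max(step, 1))
  starts <- floor(k * step)
  starts <- starts[starts + tau <= n]
  if (length(starts) < 2L)
    stop(sprintf("window length %d samples: fewer than 2 windows fit in %d",
                 tau, n))
  idx <- outer(seq_len(tau), starts, `+`)      # tau x nwin indices
  w <- matrix(profile[idx], nrow = tau)
  tt <- seq_len(tau)
  x <- cbind(1, tt)
  beta <- solve(crossprod(x), crossprod(x, w)) # 2 x nwin
  resid <- w - x %*% beta
  mean(sqrt(colSums(resid^2) / tau))
}

#' Detrended fluctuation analysis of a series
#'
#' Full DFA: builds the signal profile, evaluates the fluctuation function
#' over log-spaced window lengths, and fits an ordinary least-squares line
#' to log10 F(tau) versus log10 tau. The slope is the DFA exponent alpha
#' (0.5 for an uncorrelated series; 0.5 < alpha < 1 indicates persistent
#' long-range temporal correlation), reported with the R^2 of that fit.
#'
#' @param x the series to analyse (e.g. a TV-PS series), or a
#'   [TVPSSeries-class].
#' @param fs sampling rate in Hz (taken from \code{x} when it is a
#'   TVPSSeries).
#' @param minS,maxS window range in seconds (defaults 1 and 15).
#' @param nTau number of window lengths (default 15).
#' @param overlap fractional window overlap (default 0.5).
#' @param taus optional explicit window lengths in samples, overriding the
#'   range arguments.
#' @return a [DFAResult-class].
#' @examples
#' r <- fitDFA(rnorm(8192), fs = 250)
#' dfaAlpha(r)  # ~0.5
#' @export
fitDFA <- function(x, fs = NULL, minS = 1, maxS = 15, nTau = 15L,
                   overlap = 0.5, taus = NULL) {
  if (methods::is(x, "TVPSSeries")) {
    if (is.null(fs)) fs <- x@fs
    x <- x@values
  }
  if (is.null(fs)) stop("'fs' is required")
  if (is.null(taus))
    taus <- windowLengths(minS, maxS, nTau, fs, n = length(x))
  else {
    taus <- sort(unique(as.integer(taus)))
    if (any(taus > length(x) / 2))
      stop("largest window must fit at least twice in the series")
  }
  prof <- signalProfile(x)
  f <- vapply(taus, function(tau) fluctuationFunction(prof, tau, overlap),
              numeric(1))
  if (any(f <= 0))
    stop("degenerate series: zero fluctuation at some window length")
  tauS <- taus / fs
  lt <- log10(tauS); lf <- log10(f)
  fit <- stats::lm.fit(cbind(1, lt), lf)
  alpha <- unname(fit$coefficients[2L])
  r2 <- 1 - sum(fit$residuals^2) / sum((lf - mean(lf))^2)
  plot <- methods::new("FluctuationPlot", tauS = tauS,
                       tauSamples = as.integer(taus),
                       log10Tau = lt, log10F = lf)
  methods::new("DFAResult", alpha = alpha, rSquared = r2, plot = plot)
}

#' Band-specific minimum DFA window
#'
#' Slow bands need longer minimum windows for the smallest window to hold
#' a few oscillation cycles: 2 s for delta and theta (lower edge below
#' 8 Hz), 1 s otherwise.
#'
#' @param band band name or definition.
#' @return minimum window length in seconds.
#' @export
bandMinTauS <- function(band) {
  if (resolveBand(band)$low_hz < 8) 2 else 1
}
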