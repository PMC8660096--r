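#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' SourceDataset: a multi-subject collection of ROI source time series
#'
#' Container for band-limited (or broadband) source-activity time series of
#' one cohort: one numeric matrix (ROIs x time) per subject, a shared
#' sampling rate, and a subject table carrying the group label and age used
#' downstream as regressor and nuisance covariate.
#'
#' @slot signals list of numeric matrices, one per subject, all of identical
#'   dimension (ROIs x samples); rownames are ROI labels.
#' @slot fs sampling rate in Hz.
#' @slot subjects [S4Vectors::DataFrame] with columns \code{id},
#'   \code{group} (factor with exactly two levels) and \code{age} (years).
#' @slot metadata list of free-form provenance (generator spec, seed, band).
#'
#' @exportClass SourceDataset
setClass("SourceDataset",
  representation(
    signals  = "list",
    fs       = "numeric",
    subjects = "DataFrame",
    metadata = "list"
  )
)

setValidity("SourceDataset", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@signals) != nrow(object@subjects))
    msg <- c(msg, "one signal matrix per subject row is required")
  if (length(object@signals)) {
    dims <- vapply(object@signals, dim, integer(2))
    if (!all(dims[1, ] == dims[1, 1]) || !all(dims[2, ] == dims[2, 1]))
      msg <- c(msg, "all subjects must share ROI count and series length")
  }
  grp <- object@subjects$group
  if (!is.null(grp) && nlevels(droplevels(as.factor(grp))) != 2L)
    msg <- c(msg, "'group' must take exactly two values")
  if (length(msg)) msg else TRUE
})

#' PhaseSeries: wrapped and unwrapped instantaneous phase of one signal
#'
#' @slot wrapped phase in radians, each value in [-pi, pi].
#' @slot unwrapped continuous phase in radians (multiples of 2*pi added at
#'   wrap events).
#' @slot fs sampling rate in Hz.
#' @exportClass PhaseSeries
setClass("PhaseSeries",
  representation(wrapped = "numeric", unwrapped = "numeric", fs = "numeric")
)

setValidity("PhaseSeries", function(object) {
  msg <- character()
  if (length(object@wrapped) != length(object@unwrapped))
    msg <- c(msg, "wrapped and unwrapped phase must have equal length")
  if (any(abs(object@wrapped) > pi + 1e-9))
    msg <- c(msg, "wrapped phase must lie in [-pi, pi]")
  if (length(msg)) msg else TRUE
})

#' TVPSSeries: rate of change of the unwrapped phase difference
#'
#' The time-varying phase synchrony (TV-PS) series of one ROI pair: the
#' first difference of the unwrapped phase difference, in radians per
#' sample. Together with \code{initialPhaseDiff} it reconstructs the
#' unwrapped phase difference exactly.
#'
#' @slot roiA,roiB 1-based ROI indices with \code{roiA < roiB}.
#' @slot values first difference of the unwrapped phase difference
#'   (radians/sample); length is one less than the (trimmed) phase length.
#' @slot initialPhaseDiff unwrapped phase difference at the first retained
#'   sample (radians).
#' @slot fs sampling rate in Hz.
#' @exportClass TVPSSeries
setClass("TVPSSeries",
  representation(roiA = "integer", roiB = "integer", values = "numeric",
                 initialPhaseDiff = "numeric", fs = "numeric")
)

#' FluctuationPlot: the (log10 tau, log10 F) points from DFA windowing
#'
#' @slot tauS window lengths in seconds, strictly increasing.
#' @slot tauSamples integer window lengths in samples.
#' @slot log10Tau log10 of tauS.
#' @slot log10F log10 of the fluctuation function F(tau).
#' @exportClass FluctuationPlot
setClass("FluctuationPlot",
  representation(tauS = "numeric", tauSamples = "integer",
                 log10Tau = "numeric", log10F = "numeric")
)

setValidity("FluctuationPlot", function(object) {
  msg <- character()
  if (length(object@tauS) < 6L)
    msg <- c(msg, "at least 6 window lengths are required for a stable fit")
  if (is.unsorted(object@tauS, strictly = TRUE))
    msg <- c(msg, "window lengths must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' DFAResult: scaling exponent and goodness of fit of one DFA run
#'
#' @slot alpha DFA scaling exponent (slope of log10 F on log10 tau).
#' @slot rSquared coefficient of determination of the log-log fit.
#' @slot plot the underlying [FluctuationPlot-class].
#' @exportClass DFAResult
setClass("DFAResult",
  representation(alpha = "numeric", rSquared = "numeric",
                 plot = "FluctuationPlot")
)

setValidity("DFAResult", function(object) {
  msg <- character()
  if (!is.finite(object@alpha)) msg <- c(msg, "'alpha' must be finite")
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "'rSquared' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ScaleInvarianceVerdict: ML-DFA model selection outcome for one plot
#'
#' Scale-invariance is accepted if and only if the straight line attains
#' the strictly lowest AIC among all candidate models (ties count against
#' acceptance).
#'
#' @slot accepted logical verdict.
#' @slot winningModel name of the AIC-minimising model.
#' @slot fits data.frame with one row per candidate model
#'   (\code{model}, \code{nParams}, \code{rss}, \code{aic}).
#' @exportClass ScaleInvarianceVerdict
setClass("ScaleInvarianceVerdict",
  representation(accepted = "logical", winningModel = "character",
                 fits = "data.frame")
)

#' EdgeStats: per-edge GLM F statistics of a group contrast
#'
#' @slot fStat partial F statistic of the group column per edge.
#' @slot pUncorrected parametric p-value from F(1, dfDenom).
#' @slot effectSign sign of the adjusted group-1-minus-group-2 contrast.
#' @slot df numerator and denominator degrees of freedom.
#' @slot pairs two-column integer matrix of ROI pairs (a < b), one row per
#'   edge.
#' @slot direction which one-sided alternative the screening retains:
#'   \code{"group1>group2"}, \code{"group2>group1"} or \code{"two.sided"}.
#' @exportClass EdgeStats
setClass("EdgeStats",
  representation(fStat = "numeric", pUncorrected = "numeric",
                 effectSign = "numeric", df = "numeric",
                 pairs = "matrix", direction = "character")
)

#' NBSResult: network-based statistic inference for one contrast
#'
#' @slot components data.frame with one row per observed supra-threshold
#'   connected component: \code{extent}, \code{intensity}, \code{pFwer},
#'   and an \code{edges} list column of two-column pair matrices.
#' @slot edgeStats the observed [EdgeStats-class].
#' @slot nullMaxSize permutation null distribution of the maximal component
#'   size (length nPerm).
#' @slot pPrimary primary (uncorrected) edge threshold.
#' @slot sizeMode \code{"extent"} or \code{"intensity"}.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used for the permutations (NA if none supplied).
#' @exportClass NBSResult
setClass("NBSResult",
  representation(components = "data.frame", edgeStats = "EdgeStats",
                 nullMaxSize = "numeric", pPrimary = "numeric",
                 sizeMode = "character", nPerm = "integer", seed = "numeric")
)

#' SyntheticSpec: parameters of the synthetic cohort generator
#'
#' @slot nRois number of ROIs.
#' @slot nSubjectsPerGroup subject counts for group 1 and group 2.
#' @slot durationS recording duration in seconds.
#' @slot fs sampling rate in Hz.
#' @slot carrierBand one-row data.frame (name, low_hz, high_hz) giving the
#'   narrow band of the simulated oscillations.
#' @slot baselineHurst Hurst exponent of pairwise phase-difference
#'   increments everywhere no effect is planted, in (0, 1).
#' @slot effectHurst Hurst exponent planted on \code{effectEdges} in
#'   group 2, in (0, 1).
#' @slot effectEdges two-column integer matrix of ROI pairs carrying the
#'   planted group effect (may have zero rows).
#' @slot ageRange age range in years, ages drawn uniformly.
#' @slot ageSlope optional change of the effective baseline Hurst exponent
#'   per year of age (0 = no age confound).
#' @slot phaseScale standard deviation of the phase-difference increments
#'   in radians per sample.
#' @slot jitterSd standard deviation of the common carrier phase jitter
#'   (radians per sample), shared by all ROIs of a subject.
#' @slot noiseAmp amplitude of additive broadband white noise relative to
#'   the unit-amplitude oscillation.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    nRois = "integer", nSubjectsPerGroup = "integer",
    durationS = "numeric", fs = "numeric", carrierBand = "data.frame",
    baselineHurst = "numeric", effectHurst = "numeric",
    effectEdges = "matrix", ageRange = "numeric", ageSlope = "numeric",
    phaseScale = "numeric", jitterSd = "numeric", noiseAmp = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nRois < 2L) msg <- c(msg, "'nRois' must be at least 2")
  if (length(object@nSubjectsPerGroup) != 2L ||
      any(object@nSubjectsPerGroup < 1L))
    msg <- c(msg, "'nSubjectsPerGroup' must be two positive counts")
  for (h in c(baseline = object@baselineHurst, effect = object@effectHurst))
    if (h <= 0 || h >= 1)
      msg <- c(msg, "Hurst exponents must lie strictly in (0, 1)")
  ee <- object@effectEdges
  if (nrow(ee)) {
    if (ncol(ee) != 2L) msg <- c(msg, "'effectEdges' needs two columns")
    else if (any(ee < 1L) || any(ee > object@nRois))
      msg <- c(msg, "'effectEdges' references an ROI outside 1..nRois")
    else if (any(ee[, 1] == ee[, 2]))
      msg <- c(msg, "'effectEdges' must be pairs of distinct ROIs")
  }
  if (diff(object@ageRange) < 0)
    msg <- c(msg, "'ageRange' must be increasing")
  if (length(msg)) msg else TRUE
})
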