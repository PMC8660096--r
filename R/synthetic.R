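#' @include AllClasses.R bands.R
NULL

#' Construct a synthetic cohort specification
#'
#' Parameters of the synthetic resting-state cohort the generators
#' emulate: two groups of subjects (default 27 + 25, ages 5-18 years,
#' 300 s recordings at 250 Hz, 84 ROIs), narrow-band oscillations in a
#' carrier band, pairwise phase-difference increments that are fractional
#' Gaussian noise with a known Hurst exponent, and an optional planted
#' set of ROI pairs whose phase-synchrony Hurst exponent is lowered in
#' group 2.
#'
#' @param nRois number of ROIs (default 84).
#' @param nSubjectsPerGroup counts for group 1 and group 2 (default
#'   c(27, 25)).
#' @param durationS recording duration in seconds (default 300).
#' @param fs sampling rate in Hz (default 250).
#' @param carrierBand band name or definition of the simulated
#'   oscillation (default "high-gamma").
#' @param baselineHurst Hurst exponent everywhere no effect is planted
#'   (default 0.75).
#' @param effectEdges two-column matrix of ROI pairs carrying the planted
#'   group effect (default none).
#' @param effectHurst Hurst exponent of the planted edges in group 2
#'   (default 0.55).
#' @param ageRange ages drawn uniformly from this range (default
#'   c(5, 18)).
#' @param ageSlope change of effective baseline Hurst per year of age
#'   (default 0: ages carry no effect and act purely as a nuisance
#'   covariate).
#' @param phaseScale sd of phase-difference increments, radians/sample
#'   (default 0.05, small enough to keep the oscillation inside its
#'   nominal band).
#' @param jitterSd sd of the common carrier phase jitter shared by all
#'   ROIs of a subject (default 0.02 rad/sample).
#' @param noiseAmp amplitude of additive broadband white noise (default
#'   0.05 relative to the unit oscillation), giving every band some
#'   non-degenerate content.
#' @param seed integer RNG seed (default 1).
#' @return a [SyntheticSpec-class].
#' @examples
#' syntheticSpec(nRois = 10, nSubjectsPerGroup = c(8, 8), durationS = 60)
#' @export
syntheticSpec <- function(nRois = 84, nSubjectsPerGroup = c(27, 25),
                          durationS = 300, fs = 250,
                          carrierBand = "high-gamma",
                          baselineHurst = 0.75, effectEdges = NULL,
                          effectHurst = 0.55, ageRange = c(5, 18),
                          ageSlope = 0, phaseScale = 0.05,
                          jitterSd = 0.02, noiseAmp = 0.05, seed = 1L) {
  if (is.null(effectEdges))
    effectEdges <- matrix(integer(), ncol = 2)
  effectEdges <- matrix(as.integer(effectEdges), ncol = 2)
  # canonical a < b orientation
  if (nrow(effectEdges))
    effectEdges <- t(apply(effectEdges, 1L, sort))
  methods::new("SyntheticSpec",
    nRois = as.integer(nRois),
    nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
    durationS = durationS, fs = fs,
    carrierBand = resolveBand(carrierBand),
    baselineHurst = baselineHurst, effectHurst = effectHurst,
    effectEdges = effectEdges, ageRange = as.numeric(ageRange),
    ageSlope = ageSlope, phaseScale = phaseScale, jitterSd = jitterSd,
    noiseAmp = noiseAmp, seed = as.integer(seed))
}

# carrier phase ramp plus common jitter walk, shared by all ROIs
carrierPhase <- function(n, fc, fs, jitterSd) {
  2 * pi * fc * (0:(n - 1L)) / fs +
    if (jitterSd > 0) cumsum(stats::rnorm(n, 0, jitterSd)) else 0
}

#' Simulate an oscillator pair with a prescribed phase-synchrony Hurst
#' exponent
#'
#' Two narrow-band oscillators at the carrier band's midpoint whose
#' unwrapped phase difference is a scaled cumulative sum of fractional
#' Gaussian noise with Hurst exponent \code{hurst}: the TV-PS series the
#' pipeline extracts from the pair is, up to filtering distortion, fGn
#' with that exponent. A common phase jitter shared by both oscillators
#' leaves the pairwise difference untouched.
#'
#' @param hurst ground-truth Hurst exponent of the phase-difference
#'   increments, in (0, 1).
#' @param band carrier band name or definition.
#' @param durationS duration in seconds; must cover the largest DFA
#'   window at least twice (default window range tops at
#'   \code{maxTauS} = 15 s, so durationS >= 30).
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed.
#' @param phaseScale sd of the phase-difference increments
#'   (radians/sample, default 0.05); 0 gives two identical oscillators
#'   (TV-PS identically zero downstream) when \code{noiseAmp} is also 0.
#' @param jitterSd common carrier jitter sd (default 0.02).
#' @param noiseAmp additive white-noise amplitude (default 0.05).
#' @param maxTauS largest DFA window the signals must support (default
#'   15 s).
#' @return list with numeric series \code{a} and \code{b} and the planted
#'   increments \code{increments} (the scaled fGn the phase difference
#'   accumulates).
#' @examples
#' pr <- simulatePhaseCoupledPair(0.75, "alpha", 60, 250, seed = 1)
#' @export
simulatePhaseCoupledPair <- function(hurst, band, durationS, fs,
                                     seed = NULL, phaseScale = 0.05,
                                     jitterSd = 0.02, noiseAmp = 0.05,
                                     maxTauS = 15) {
  band <- resolveBand(band)
  fc <- (band$low_hz + band$high_hz) / 2
  if (fc >= fs / 2) stop("carrier frequency must be below Nyquist")
  if (durationS < 2 * maxTauS)
    stop(sprintf(
      "duration %g s too short: the largest DFA window (%g s) must fit twice",
      durationS, maxTauS))
  n <- as.integer(round(durationS * fs))
  withSeed(seed, {
    phi0 <- carrierPhase(n, fc, fs, jitterSd)
    inc <- if (phaseScale > 0) phaseScale * simulateFGN(n, hurst)
           else numeric(n)
    delta <- cumsum(inc)
    a <- cos(phi0)
    b <- cos(phi0 + delta)
    if (noiseAmp > 0) {
      a <- a + noiseAmp * stats::rnorm(n)
      b <- b + noiseAmp * stats::rnorm(n)
    }
    list(a = a, b = b, increments = inc)
  })
}

# spanning forest of the planted edge set as (parent, child) rows in BFS
# order, so a parent's phase walk is always defined before its children's
effectForest <- function(effectEdges, nRois) {
  adj <- vector("list", nRois)
  for (k in seq_len(nrow(effectEdges))) {
    a <- effectEdges[k, 1L]; b <- effectEdges[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  visited <- logical(nRois)
  out <- NULL
  for (root in sort(unique(as.vector(effectEdges)))) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in sort(adj[[v]])) if (!visited[w]) {
        visited[w] <- TRUE
        out <- rbind(out, c(parent = v, child = w))
        queue <- c(queue, w)
      }
    }
  }
  out
}

#' Simulate a two-group multi-ROI cohort with planted connectome effects
#'
#' Generates a [SourceDataset-class] of narrow-band oscillatory ROI
#' signals whose pairwise phase-difference increments are fractional
#' Gaussian noise. Each ROI carries an independent baseline phase walk
#' (Hurst = baselineHurst). The planted edges are arranged as a spanning
#' forest along which each child ROI's phase is the parent's phase plus
#' an edge-specific walk: in group 2 those edge walks use
#' \code{effectHurst}, in group 1 \code{baselineHurst}, so exactly the
#' planted pairs differ between groups while everything else stays at
#' baseline. Ages are drawn uniformly and by default carry no effect.
#'
#' @param spec a [SyntheticSpec-class] (see [syntheticSpec]).
#' @return a [SourceDataset-class]; generation is fully reproducible from
#'   \code{spec} (including its seed).
#' @examples
#' ds <- simulateGroupDataset(syntheticSpec(nRois = 4,
#'   nSubjectsPerGroup = c(3, 3), durationS = 40, fs = 250))
#' dim(ds)
#' @export
simulateGroupDataset <- function(spec) {
  methods::validObject(spec)
  n <- as.integer(round(spec@durationS * spec@fs))
  fc <- (spec@carrierBand$low_hz + spec@carrierBand$high_hz) / 2
  if (fc >= spec@fs / 2) stop("carrier frequency must be below Nyquist")
  nSub <- sum(spec@nSubjectsPerGroup)
  groups <- rep(c("group1", "group2"), spec@nSubjectsPerGroup)
  forest <- if (nrow(spec@effectEdges))
    effectForest(spec@effectEdges, spec@nRois) else NULL

  withSeed(spec@seed, {
    ages <- stats::runif(nSub, spec@ageRange[1], spec@ageRange[2])
    signals <- vector("list", nSub)
    for (s in seq_len(nSub)) {
      hBase <- spec@baselineHurst +
        spec@ageSlope * (ages[s] - mean(spec@ageRange))
      hBase <- min(max(hBase, 0.05), 0.95)
      hEdge <- if (groups[s] == "group2") spec@effectHurst else hBase
      phi0 <- carrierPhase(n, fc, spec@fs, spec@jitterSd)
      theta <- matrix(0, spec@nRois, n)
      inTree <- if (is.null(forest)) integer() else unique(forest[, "child"])
      for (r in seq_len(spec@nRois)) {
        if (!(r %in% inTree))
          theta[r, ] <- cumsum(spec@phaseScale * simulateFGN(n, hBase))
      }
      if (!is.null(forest)) {
        for (k in seq_len(nrow(forest))) {
          pa <- forest[k, "parent"]; ch <- forest[k, "child"]
          theta[ch, ] <- theta[pa, ] +
            cumsum(spec@phaseScale * simulateFGN(n, hEdge))
        }
      }
      m <- cos(sweep(theta, 2L, phi0, `+`))
      if (spec@noiseAmp > 0)
        m <- m + spec@noiseAmp * matrix(stats::rnorm(spec@nRois * n),
                                        spec@nRois, n)
      rownames(m) <- paste0("ROI", seq_len(spec@nRois))
      signals[[s]] <- m
    }
    subjects <- S4Vectors::DataFrame(
      id = sprintf("s%03d", seq_len(nSub)),
      group = factor(groups, levels = c("group1", "group2")),
      age = ages)
    methods::new("SourceDataset", signals = signals, fs = spec@fs,
                 subjects = subjects,
                 metadata = list(spec = spec, seed = spec@seed,
                                 carrierBand = spec@carrierBand))
  })
}
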