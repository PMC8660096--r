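#' @include AllClasses.R
NULL

#' The thirteen ML-DFA candidate models
#'
#' Scale-invariance validation fits the fluctuation plot (in log-log
#' space) with 13 competing models: polynomials of degree 1-5 (linear,
#' quadratic, cubic, quartic, quintic), root laws a + b * u^(1/k) for
#' k = 2, 3, 4, an exponential a + b * exp(c * u), a logarithm
#' a + b * log(x - c) with c constrained below min(x), and continuous
#' piecewise-linear splines with 2, 3 and 4 sections. (u denotes the
#' abscissa shifted to start at 0 so fractional powers are defined.)
#' Spline parameter counts are the k + 1 regression coefficients of a
#' k-section continuous piecewise-linear fit; the breakpoints, found by
#' exhaustive search, are not counted.
#'
#' @return data.frame with columns \code{model} and \code{nParams},
#'   13 rows.
#' @examples
#' nrow(candidateModels())  # 13
#' @export
candidateModels <- function() {
  data.frame(
    model = c("linear", "quadratic", "cubic", "quartic", "quintic",
              "root2", "root3", "root4", "exponential", "logarithmic",
              "spline2", "spline3", "spline4"),
    nParams = c(2L, 3L, 4L, 5L, 6L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 5L),
    stringsAsFactors = FALSE
  )
}

# least-squares fit on a design matrix; NULL if rank-deficient
lsFit <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)
  list(rss = sum(fit$residuals^2), fitted = y - as.numeric(fit$residuals))
}

# continuous piecewise-linear design: [1, x, (x-b1)+, (x-b2)+, ...]
hingeDesign <- function(x, breaks) {
  X <- cbind(1, x)
  for (b in breaks) X <- cbind(X, pmax(x - b, 0))
  X
}

# exhaustive spline fit: breakpoints chosen among interior abscissae
fitSpline <- function(x, y, nSections) {
  interior <- x[-c(1L, length(x))]
  nb <- nSections - 1L
  if (length(interior) < nb) return(NULL)
  combos <- utils::combn(interior, nb)
  best <- NULL
  for (j in seq_len(ncol(combos))) {
    f <- lsFit(hingeDesign(x, combos[, j]), y)
    if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
  }
  best
}

# 1-D profiled nonlinear fits: grid over the nonlinear parameter with a
# linear solve for (a, b), then a local golden-section refinement
profiledFit <- function(x, y, grid, design) {
  fitAt <- function(p) lsFit(design(p), y)
  rssAt <- function(p) {
    f <- fitAt(p)
    if (is.null(f)) Inf else f$rss
  }
  vals <- vapply(grid, rssAt, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  pBest <- grid[i]
  if (lo < hi) {
    opt <- stats::optimize(rssAt, c(lo, hi))
    if (opt$objective < vals[i]) pBest <- opt$minimum
  }
  fitAt(pBest)
}

# normalised-curve log-likelihood: map the plot onto [0,1] vertically,
# treat data heights (plus a small offset) as a probability mass over the
# window lengths, and score a fitted curve by the cross-entropy of its
# similarly normalised heights, scaled by an effective observation count.
# This deliberately measures the *shape* mismatch of the whole curve
# rather than pointwise residuals: fluctuation-plot points are strongly
# correlated (windows overlap and share one series), so an iid Gaussian
# residual likelihood grossly overstates the evidence for wiggle-chasing
# models.
mldfaLogLik <- function(y, fitted, nEff, offset = 0.1) {
  rng <- max(y) - min(y)
  if (rng <= 0) rng <- 1
  p <- (y - min(y)) / rng + offset
  p <- p / sum(p)
  q <- (fitted - min(y)) / rng + offset
  q <- pmax(q, 1e-12)
  q <- q / sum(q)
  nEff * sum(p * log(q))
}

# effective observation count of the normalised likelihood (see the
# methods vignette for its calibration on fractional-Gaussian-noise
# reference plots)
.mldfaNEff <- 300

#' Fit one ML-DFA candidate model to a fluctuation plot
#'
#' Least-squares fit of one of the 13 candidates (see [candidateModels])
#' to the (log10 tau, log10 F) points. Spline breakpoints are found by
#' exhaustive search over interior abscissae; the exponential and
#' logarithmic shapes are profiled over their nonlinear parameter on a
#' deterministic grid with local refinement. The reported AIC is
#' 2 * nParams - 2 * logLik with the normalised-curve likelihood
#' described in the package vignette; the raw residual sum of squares of
#' the least-squares fit is reported alongside.
#'
#' @param plot a [FluctuationPlot-class].
#' @param model model name from [candidateModels].
#' @return one-row data.frame: \code{model}, \code{nParams}, \code{rss},
#'   \code{aic}.
#' @export
fitCandidate <- function(plot, model) {
  x <- plot@log10Tau
  y <- plot@log10F
  n <- length(x)
  defs <- candidateModels()
  i <- match(model, defs$model)
  if (is.na(i)) stop(sprintf("unknown candidate model '%s'", model))
  p <- defs$nParams[i]
  if (n < p + 1L)
    stop(sprintf("underdetermined fit: %d points for %d parameters", n, p))
  u <- x - min(x)
  span <- max(diff(range(x)), .Machine$double.eps)
  fit <- switch(model,
    linear    = lsFit(cbind(1, x), y),
    quadratic = lsFit(cbind(1, stats::poly(x, 2)), y),
    cubic     = lsFit(cbind(1, stats::poly(x, 3)), y),
    quartic   = lsFit(cbind(1, stats::poly(x, 4)), y),
    quintic   = lsFit(cbind(1, stats::poly(x, 5)), y),
    root2     = lsFit(cbind(1, u^(1 / 2)), y),
    root3     = lsFit(cbind(1, u^(1 / 3)), y),
    root4     = lsFit(cbind(1, u^(1 / 4)), y),
    exponential = profiledFit(x, y,
      grid = setdiff(seq(-6, 6, by = 0.25), 0) / span,
      design = function(cc) cbind(1, exp(cc * u))),
    logarithmic = profiledFit(x, y,
      grid = log(span * 10^seq(-4, 1, by = 0.125)),
      design = function(ld) cbind(1, log(x - (min(x) - exp(ld))))),
    spline2  = fitSpline(x, y, 2L),
    spline3  = fitSpline(x, y, 3L),
    spline4  = fitSpline(x, y, 4L),
    stop("unreachable")
  )
  if (is.null(fit))
    stop(sprintf("model '%s' could not be fitted (rank-deficient design)",
                 model))
  data.frame(model = model, nParams = p, rss = fit$rss,
             aic = 2 * p - 2 * mldfaLogLik(y, fit$fitted, .mldfaNEff),
             stringsAsFactors = FALSE)
}

#' Validate scale-invariance of a fluctuation plot (ML-DFA)
#'
#' Fits all 13 candidate models and accepts scale-invariance if and only
#' if the straight line has the strictly lowest AIC; AIC ties (within
#' 1e-9) resolve against acceptance.
#'
#' @param plot a [FluctuationPlot-class].
#' @return a [ScaleInvarianceVerdict-class].
#' @export
validateScaleInvariance <- function(plot) {
  fits <- do.call(rbind, lapply(candidateModels()$model,
                                function(m) fitCandidate(plot, m)))
  winner <- fits$model[which.min(fits$aic)]
  aicLinear <- fits$aic[fits$model == "linear"]
  accepted <- all(aicLinear < fits$aic[fits$model != "linear"] - 1e-9)
  methods::new("ScaleInvarianceVerdict", accepted = accepted,
               winningModel = if (accepted) "linear" else winner,
               fits = fits)
}

#' Percentage of verdicts accepting scale-invariance
#'
#' @param verdicts a logical vector, or a list of
#'   [ScaleInvarianceVerdict-class] objects.
#' @return percentage in [0, 100].
#' @examples
#' acceptanceRate(c(TRUE, TRUE, FALSE, TRUE))  # 75
#' @export
acceptanceRate <- function(verdicts) {
  if (is.list(verdicts))
    verdicts <- vapply(verdicts, isAccepted, logical(1))
  if (!length(verdicts)) stop("at least one verdict is required")
  100 * mean(verdicts)
}
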