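#' @include AllClasses.R
NULL

# normalise group input to a two-level factor; error if not exactly 2 levels
asGroupFactor <- function(group) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2L) stop("'group' must take exactly two values")
  if (min(table(g)) < 3L) stop("at least 3 subjects per group are required")
  g
}

# design matrices for the GLM: reduced = [1, covariates], full adds the
# group-1 indicator (so a positive coefficient means group 1 > group 2).
# Covariate columns adding no rank to the reduced design (e.g. constants,
# duplicates) are dropped, so a constant covariate reproduces the
# no-covariate analysis exactly.
nbsDesigns <- function(group, covariates, n) {
  Xr <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match subjects")
    Xr2 <- cbind(Xr, covariates)
    q <- qr(Xr2)
    Xr <- Xr2[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
  }
  Xf <- cbind(Xr, group1 = as.numeric(group == levels(group)[1L]))
  if (qr(Xf)$rank < ncol(Xf))
    stop("rank-deficient design: covariates are collinear with the group")
  list(reduced = Xr, full = Xf)
}

# vectorised partial F over all edge columns of y for one full design
edgeFCore <- function(y, Xf, Xr, qrR = qr(Xr)) {
  qrF <- qr(Xf)
  rf <- qr.resid(qrF, y)
  rr <- qr.resid(qrR, y)
  rssF <- colSums(rf^2)
  rssR <- colSums(rr^2)
  df2 <- nrow(y) - ncol(Xf)
  f <- (rssR - rssF) / (rssF / df2)
  f[rssF <= 0] <- Inf
  f[f < 0] <- 0  # numerical guard
  coefG <- qr.coef(qrF, y)[ncol(Xf), ]
  list(f = f, df2 = df2, sign = sign(coefG))
}

#' Per-edge GLM F statistics of a group contrast
#'
#' For every edge (column of \code{y}) fits the general linear model with
#' an intercept, the nuisance covariates, and the group indicator, and
#' returns the partial F test of the group column (numerator df 1). A
#' one-sided \code{direction} marks as screened-out the edges whose
#' adjusted group contrast has the wrong sign; those edges never survive
#' the primary threshold.
#'
#' @param y numeric matrix, subjects x edges (e.g. DFA exponents).
#' @param group two-level group labels, length nrow(y); the first factor
#'   level is "group 1".
#' @param covariates optional numeric vector/matrix of nuisance regressors
#'   (e.g. age), one row per subject.
#' @param pairs two-column integer matrix of ROI pairs, one row per edge
#'   (defaults to all pairs of the smallest n with C(n,2) = ncol(y)).
#' @param direction \code{"group1>group2"}, \code{"group2>group1"} or
#'   \code{"two.sided"}.
#' @return an [EdgeStats-class].
#' @examples
#' y <- matrix(rnorm(20 * 10), 20)
#' st <- edgeFStats(y, rep(c("a", "b"), each = 10), pairs = roiPairs(5))
#' @export
edgeFStats <- function(y, group, covariates = NULL, pairs = NULL,
                       direction = c("two.sided", "group1>group2",
                                     "group2>group1")) {
  direction <- match.arg(direction)
  y <- as.matrix(y)
  group <- asGroupFactor(group)
  if (length(group) != nrow(y)) stop("'group' length must match subjects")
  if (is.null(pairs)) {
    nroi <- (1 + sqrt(1 + 8 * ncol(y))) / 2
    if (nroi != round(nroi))
      stop("'pairs' is required when ncol(y) is not a C(n,2)")
    pairs <- roiPairs(nroi)
  }
  if (nrow(pairs) != ncol(y)) stop("one pair per edge column is required")
  d <- nbsDesigns(group, covariates, nrow(y))
  core <- edgeFCore(y, d$full, d$reduced)
  methods::new("EdgeStats",
    fStat = unname(core$f),
    pUncorrected = stats::pf(core$f, 1, core$df2, lower.tail = FALSE),
    effectSign = unname(core$sign), df = c(1, core$df2),
    pairs = pairs, direction = direction)
}

# logical: does an edge's sign pass the one-sided screen?
signScreen <- function(effectSign, direction) {
  switch(direction,
    "two.sided"     = rep(TRUE, length(effectSign)),
    "group1>group2" = effectSign > 0,
    "group2>group1" = effectSign < 0)
}

#' Primary (uncorrected) edge threshold
#'
#' Retains the edges whose parametric p-value falls below
#' \code{pPrimary} and whose effect sign matches the tested direction,
#' as an edge list over ROIs.
#'
#' @param stats an [EdgeStats-class].
#' @param pPrimary uncorrected threshold probability (default 0.005).
#' @return two-column matrix of surviving ROI pairs with the per-edge F
#'   values as attribute \code{"f"} and the equivalent F threshold (the
#'   1 - pPrimary quantile of F(1, dfDenom)) as attribute \code{"fThreshold"}.
#' @export
primaryThreshold <- function(stats, pPrimary = 0.005) {
  if (pPrimary <= 0 || pPrimary >= 1)
    stop("'pPrimary' must lie strictly in (0, 1)")
  keep <- stats@pUncorrected < pPrimary &
    signScreen(stats@effectSign, stats@direction)
  out <- stats@pairs[keep, , drop = FALSE]
  attr(out, "f") <- stats@fStat[keep]
  attr(out, "fThreshold") <- stats::qf(1 - pPrimary, stats@df[1], stats@df[2])
  out
}

#' Connected components of supra-threshold edges
#'
#' Partitions a set of supra-threshold edges into maximal connected graph
#' components (edge sets within which any two ROIs are joined by a path)
#' and reports each component's extent (edge count) and intensity (sum of
#' edge F statistics).
#'
#' @param edges two-column matrix of ROI pairs (e.g. from
#'   [primaryThreshold]).
#' @param f per-edge statistic values, one per row of \code{edges}
#'   (defaults to attribute \code{"f"} of \code{edges}).
#' @return data.frame with columns \code{extent}, \code{intensity} and a
#'   list column \code{edges} of per-component pair matrices; zero rows
#'   when no edges are given.
#' @examples
#' findComponents(rbind(c(1, 2), c(2, 3), c(4, 5)), f = c(1, 2, 3))
#' @export
findComponents <- function(edges, f = attr(edges, "f")) {
  empty <- data.frame(extent = integer(), intensity = numeric())
  empty$edges <- list()
  if (is.null(edges) || nrow(edges) == 0L) return(empty)
  if (is.null(f)) stop("per-edge statistics 'f' are required")
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges[, 1:2]), ncol = 2), directed = FALSE)
  memb <- igraph::components(g)$membership
  edgeComp <- memb[as.character(edges[, 1])]
  comps <- sort(unique(edgeComp))
  out <- data.frame(
    extent = vapply(comps, function(cc) sum(edgeComp == cc), integer(1)),
    intensity = vapply(comps, function(cc) sum(f[edgeComp == cc]),
                       numeric(1)))
  out$edges <- lapply(comps, function(cc)
    edges[edgeComp == cc, 1:2, drop = FALSE])
  out[order(-out$extent), , drop = FALSE]
}

# max component size of one thresholded stat vector (0 when empty)
maxComponentSize <- function(f, p, sign, keepSign, pairs, pPrimary,
                             sizeMode) {
  keep <- p < pPrimary & keepSign
  if (!any(keep)) return(0)
  comp <- findComponents(pairs[keep, , drop = FALSE], f[keep])
  if (!nrow(comp)) return(0)
  max(if (sizeMode == "extent") comp$extent else comp$intensity)
}

#' Network-based statistic with permutation FWER control
#'
#' The NBS test of a group effect on a subject x edge matrix: per-edge GLM
#' partial F statistics with nuisance covariates, a primary uncorrected
#' threshold, connected components of the surviving edges, and a
#' family-wise-corrected p-value per component from the permutation null
#' distribution of the maximal component size. Each permutation randomly
#' reallocates subjects to two groups of the original sizes; covariates
#' travel with their subjects. The corrected p-value is
#' (1 + #\{null >= observed\}) / (1 + nPerm), so it can never be below
#' 1 / (nPerm + 1).
#'
#' @inheritParams edgeFStats
#' @param pPrimary primary uncorrected threshold (default 0.005).
#' @param nPerm number of permutations (default 5000, minimum 100).
#' @param sizeMode component size measure, \code{"extent"} (edge count) or
#'   \code{"intensity"} (sum of F); component membership is identical
#'   under both, only p-values may differ.
#' @param seed optional integer seed for the permutations.
#' @return an [NBSResult-class].
#' @export
nbsTest <- function(y, group, covariates = NULL, pairs = NULL,
                    pPrimary = 0.005, nPerm = 5000L,
                    sizeMode = c("extent", "intensity"),
                    direction = c("two.sided", "group1>group2",
                                  "group2>group1"),
                    seed = NULL) {
  sizeMode <- match.arg(sizeMode)
  direction <- match.arg(direction)
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("'nPerm' must be at least 100")
  y <- as.matrix(y)
  groupF <- asGroupFactor(group)
  obs <- edgeFStats(y, groupF, covariates, pairs, direction)
  surv <- primaryThreshold(obs, pPrimary)
  components <- findComponents(surv)
  obsSize <- if (nrow(components))
    (if (sizeMode == "extent") components$extent else components$intensity)
  else numeric()

  n <- nrow(y)
  d <- nbsDesigns(groupF, covariates, n)
  qrR <- qr(d$reduced)
  g1 <- levels(groupF)[1L]
  n1 <- sum(groupF == g1)
  nullMax <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    permIdx <- sample.int(n, n1)
    gcol <- numeric(n); gcol[permIdx] <- 1
    Xf <- cbind(d$reduced, group1 = gcol)
    core <- edgeFCore(y, Xf, d$reduced, qrR)
    p <- stats::pf(core$f, 1, core$df2, lower.tail = FALSE)
    maxComponentSize(core$f, p, core$sign,
                     signScreen(core$sign, direction),
                     obs@pairs, pPrimary, sizeMode)
  }, numeric(1)))

  components$pFwer <- vapply(obsSize, function(s)
    (1 + sum(nullMax >= s)) / (1 + nPerm), numeric(1))
  methods::new("NBSResult", components = components, edgeStats = obs,
               nullMaxSize = nullMax, pPrimary = pPrimary,
               sizeMode = sizeMode, nPerm = nPerm,
               seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}
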