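#' @include AllClasses.R bands.R dfa.R
NULL

#' Analysis run configuration
#'
#' Collects every tunable of the end-to-end analysis: the band set, the
#' sampling rate, the DFA window range per band (minimum 2 s for delta
#' and theta, 1 s otherwise; maximum 15 s, with a 20 s override available
#' as a sensitivity check), the number of log-spaced windows, the window
#' overlap, the NBS primary threshold and permutation count, the
#' component size mode, the edge-trim rule, and the seed.
#'
#' @param bands data.frame of band definitions (default
#'   [bandDefinitions]).
#' @param fs sampling rate in Hz (default 250).
#' @param tauMaxS largest DFA window in seconds (default 15).
#' @param nTau number of DFA window lengths (default 15).
#' @param overlap DFA window overlap fraction (default 0.5).
#' @param pPrimary NBS primary threshold (default 0.005).
#' @param nPerm NBS permutations (default 5000).
#' @param sizeMode NBS component size mode (default "extent").
#' @param edgeTrim samples trimmed per end after phase extraction;
#'   \code{"auto"} (default) trims one FIR order of the band.
#' @param mldfa run ML-DFA scale-invariance validation per pair (default
#'   TRUE).
#' @param seed integer seed (default 1).
#' @return a validated list of class \code{"RunConfig"}.
#' @examples
#' cfg <- runConfig(nPerm = 500)
#' @export
runConfig <- function(bands = bandDefinitions(), fs = 250, tauMaxS = 15,
                      nTau = 15L, overlap = 0.5, pPrimary = 0.005,
                      nPerm = 5000L, sizeMode = c("extent", "intensity"),
                      edgeTrim = "auto", mldfa = TRUE, seed = 1L) {
  sizeMode <- match.arg(sizeMode)
  cfg <- list(bands = bands, fs = fs, tauMaxS = tauMaxS,
              nTau = as.integer(nTau), overlap = overlap,
              pPrimary = pPrimary, nPerm = as.integer(nPerm),
              sizeMode = sizeMode, edgeTrim = edgeTrim, mldfa = mldfa,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  validateRunConfig(cfg)
  cfg
}

validateRunConfig <- function(cfg) {
  stopifnotScalar(cfg$fs, "fs")
  stopifnotScalar(cfg$tauMaxS, "tauMaxS")
  if (cfg$nTau < 6L) stop("'nTau' must be at least 6")
  if (cfg$overlap < 0 || cfg$overlap >= 1)
    stop("'overlap' must lie in [0, 1)")
  if (cfg$pPrimary <= 0 || cfg$pPrimary >= 1)
    stop("'pPrimary' must lie strictly in (0, 1)")
  if (cfg$nPerm < 100L) stop("'nPerm' must be at least 100")
  if (!identical(cfg$edgeTrim, "auto") &&
      (!is.numeric(cfg$edgeTrim) || cfg$edgeTrim < 0))
    stop("'edgeTrim' must be \"auto\" or a non-negative sample count")
  for (i in seq_len(nrow(cfg$bands))) resolveBand(cfg$bands[i, ])
  invisible(cfg)
}

#' Serialize a run configuration to YAML and back
#'
#' @param cfg a \code{RunConfig} (see [runConfig]).
#' @param path YAML file path.
#' @return \code{readRunConfig} returns a \code{RunConfig}; the
#'   round-trip through YAML reproduces the configuration exactly.
#' @export
writeRunConfig <- function(cfg, path) {
  x <- unclass(cfg)
  x$bands <- lapply(seq_len(nrow(cfg$bands)), function(i)
    as.list(cfg$bands[i, ]))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$bands <- do.call(rbind, lapply(x$bands, as.data.frame))
  do.call(runConfig, x)
}

#' Per-subject DFA and scale-invariance analysis
#'
#' The full single-subject chain for every configured band: band-pass
#' filter each ROI series, extract and unwrap phases, form the TV-PS
#' series of every ROI pair, run DFA over the band's window range, and
#' (optionally) the ML-DFA scale-invariance verdict.
#'
#' @param x ROIs x time numeric matrix for one subject.
#' @param config a \code{RunConfig} (see [runConfig]).
#' @param bands optional subset of band names to run (default: all in
#'   the config).
#' @return data.frame with one row per band x ROI pair: \code{band},
#'   \code{roiA}, \code{roiB}, \code{alpha}, \code{rSquared},
#'   \code{accepted}, \code{winningModel}.
#' @export
runSubject <- function(x, config = runConfig(), bands = NULL) {
  if (!is.matrix(x)) stop("'x' must be an ROIs x time matrix")
  bandSet <- config$bands
  if (!is.null(bands)) bandSet <- bandSet[bandSet$name %in% bands, ]
  out <- vector("list", nrow(bandSet))
  for (i in seq_len(nrow(bandSet))) {
    band <- bandSet[i, , drop = FALSE]
    series <- allPairsTVPS(x, band = band, fs = config$fs,
                           trim = config$edgeTrim)
    minS <- bandMinTauS(band)
    rows <- lapply(series, function(tv) {
      res <- tryCatch(
        fitDFA(tv, minS = minS, maxS = config$tauMaxS, nTau = config$nTau,
               overlap = config$overlap),
        error = function(e) stop(sprintf(
          "band %s, pair %d-%d: %s", band$name, tv@roiA, tv@roiB,
          conditionMessage(e)), call. = FALSE))
      verdict <- if (isTRUE(config$mldfa))
        validateScaleInvariance(fluctuationPlot(res)) else NULL
      data.frame(band = band$name, roiA = tv@roiA, roiB = tv@roiB,
                 alpha = dfaAlpha(res), rSquared = rSquared(res),
                 accepted = if (is.null(verdict)) NA else isAccepted(verdict),
                 winningModel = if (is.null(verdict)) NA_character_
                                else verdict@winningModel,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble per-subject DFA tables into a SummarizedExperiment
#'
#' Rows are band x ROI-pair features, columns are subjects; assays hold
#' the DFA exponent, the fit R^2 and the ML-DFA acceptance flag.
#'
#' @param tables named list of [runSubject] outputs, one per subject.
#' @param subjects subject table ([S4Vectors::DataFrame] or data.frame
#'   with id, group, age) in the same order.
#' @return a [SummarizedExperiment::SummarizedExperiment].
#' @export
collectDFAExperiment <- function(tables, subjects) {
  stopifnot(length(tables) == nrow(subjects))
  ref <- tables[[1]][, c("band", "roiA", "roiB")]
  pull <- function(col) {
    m <- vapply(tables, function(tb) {
      if (!identical(tb[, c("band", "roiA", "roiB")], ref))
        stop("subjects disagree on the band/pair feature set")
      tb[[col]]
    }, numeric(nrow(ref)))
    dimnames(m) <- list(NULL, subjects$id)
    m
  }
  assays <- list(alpha = pull("alpha"), rSquared = pull("rSquared"))
  if (!all(is.na(tables[[1]]$accepted)))
    assays$accepted <- pull("accepted")
  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(ref),
    colData = S4Vectors::DataFrame(subjects))
}

#' Group-level analysis: DFA per subject, then NBS per band and direction
#'
#' Runs [runSubject] for every subject of a dataset, collects the DFA
#' exponents into a [SummarizedExperiment::SummarizedExperiment], and for
#' each band performs the NBS test of a group difference in both
#' one-sided directions with age as nuisance covariate. Scale-invariance
#' acceptance-rate matrices per band and group are computed alongside.
#'
#' @param dataset a [SourceDataset-class].
#' @param config a \code{RunConfig} (see [runConfig]).
#' @param bands optional subset of band names.
#' @return list with elements \code{experiment} (the
#'   SummarizedExperiment), \code{nbs} (list of [NBSResult-class] named
#'   "<band>.<direction>"), and \code{acceptance} (per band, a list of
#'   per-group named vectors of acceptance percentages per pair, NULL
#'   when ML-DFA is disabled).
#' @export
runGroupAnalysis <- function(dataset, config = runConfig(), bands = NULL) {
  methods::validObject(dataset)
  if (samplingRate(dataset) != config$fs)
    stop("dataset and config disagree on the sampling rate")
  subj <- subjectInfo(dataset)
  tables <- lapply(seq_len(nSubjects(dataset)), function(i)
    runSubject(signalMatrix(dataset, i), config, bands))
  names(tables) <- subj$id
  se <- collectDFAExperiment(tables, subj)

  rd <- SummarizedExperiment::rowData(se)
  alpha <- SummarizedExperiment::assay(se, "alpha")
  group <- subj$group
  age <- subj$age
  bandNames <- unique(rd$band)
  nbs <- list()
  acceptance <- list()
  for (bn in bandNames) {
    sel <- rd$band == bn
    y <- t(alpha[sel, , drop = FALSE])            # subjects x edges
    pairs <- cbind(a = rd$roiA[sel], b = rd$roiB[sel])
    for (dir in c("group1>group2", "group2>group1")) {
      nbs[[paste(bn, dir, sep = ".")]] <- nbsTest(
        y, group, covariates = age, pairs = pairs,
        pPrimary = config$pPrimary, nPerm = config$nPerm,
        sizeMode = config$sizeMode, direction = dir, seed = config$seed)
    }
    if ("accepted" %in% SummarizedExperiment::assayNames(se)) {
      acc <- SummarizedExperiment::assay(se, "accepted")[sel, , drop = FALSE]
      acceptance[[bn]] <- lapply(split(seq_along(group), group), function(ix)
        stats::setNames(apply(acc[, ix, drop = FALSE], 1L,
                              function(v) acceptanceRate(v > 0)),
                        pairLabels(pairs)))
    }
  }
  list(experiment = se, nbs = nbs,
       acceptance = if (length(acceptance)) acceptance else NULL)
}
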