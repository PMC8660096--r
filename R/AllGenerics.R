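#' @include AllClasses.R
NULL

#' Accessors for tvpsDFA objects
#'
#' Small accessor generics: \code{nSubjects}, \code{nROIs},
#' \code{samplingRate}, \code{subjectInfo}, \code{signalMatrix},
#' \code{dfaAlpha}, \code{rSquared}, \code{fluctuationPlot},
#' \code{isAccepted}, \code{nbsComponents}.
#'
#' @param object a tvpsDFA S4 object.
#' @param i subject index or id (for \code{signalMatrix}).
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("nROIs", function(object) standardGeneric("nROIs"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("subjectInfo", function(object) standardGeneric("subjectInfo"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object, i) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("dfaAlpha", function(object) standardGeneric("dfaAlpha"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("fluctuationPlot", function(object) standardGeneric("fluctuationPlot"))
#' @rdname accessors
#' @export
setGeneric("isAccepted", function(object) standardGeneric("isAccepted"))
#' @rdname accessors
#' @export
setGeneric("nbsComponents", function(object) standardGeneric("nbsComponents"))

#' @rdname accessors
setMethod("nSubjects", "SourceDataset", function(object)
  length(object@signals))
#' @rdname accessors
setMethod("nROIs", "SourceDataset", function(object)
  if (length(object@signals)) nrow(object@signals[[1]]) else 0L)
#' @rdname accessors
setMethod("samplingRate", "SourceDataset", function(object) object@fs)
#' @rdname accessors
setMethod("subjectInfo", "SourceDataset", function(object) object@subjects)
#' @rdname accessors
setMethod("signalMatrix", "SourceDataset", function(object, i) {
  if (is.character(i)) i <- match(i, object@subjects$id)
  object@signals[[i]]
})
#' @rdname accessors
setMethod("samplingRate", "PhaseSeries", function(object) object@fs)
#' @rdname accessors
setMethod("dfaAlpha", "DFAResult", function(object) object@alpha)
#' @rdname accessors
setMethod("rSquared", "DFAResult", function(object) object@rSquared)
#' @rdname accessors
setMethod("fluctuationPlot", "DFAResult", function(object) object@plot)
#' @rdname accessors
setMethod("isAccepted", "ScaleInvarianceVerdict", function(object)
  object@accepted)
#' @rdname accessors
setMethod("nbsComponents", "NBSResult", function(object) object@components)

#' @describeIn accessors dimensions of a SourceDataset as
#'   (subjects, ROIs, samples).
#' @param x a SourceDataset.
#' @export
setMethod("dim", "SourceDataset", function(x)
  c(nSubjects(x), nROIs(x),
    if (length(x@signals)) ncol(x@signals[[1]]) else 0L))

setMethod("show", "SourceDataset", function(object) {
  d <- dim(object)
  grp <- table(object@subjects$group)
  cat(sprintf(
    "SourceDataset: %d subjects x %d ROIs x %d samples @ %g Hz\n",
    d[1], d[2], d[3], object@fs))
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
})

setMethod("show", "DFAResult", function(object) {
  cat(sprintf("DFAResult: alpha = %.4f, R^2 = %.4f (%d window lengths, %g-%g s)\n",
              object@alpha, object@rSquared, length(object@plot@tauS),
              min(object@plot@tauS), max(object@plot@tauS)))
})

setMethod("show", "ScaleInvarianceVerdict", function(object) {
  cat(sprintf("ScaleInvarianceVerdict: %s (winning model: %s)\n",
              if (object@accepted) "scale-invariance accepted"
              else "scale-invariance rejected",
              object@winningModel))
})

setMethod("show", "NBSResult", function(object) {
  cat(sprintf(
    "NBSResult (%s, primary p < %g, %d permutations, direction %s)\n",
    object@sizeMode, object@pPrimary, object@nPerm,
    object@edgeStats@direction))
  if (nrow(object@components)) {
    df <- object@components
    cat(sprintf("  %d supra-threshold component(s); smallest pFWER = %.4g\n",
                nrow(df), min(df$pFwer)))
  } else {
    cat("  no supra-threshold components\n")
  }
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d ROIs, %d+%d subjects, %g s @ %g Hz, band %s\n",
    object@nRois, object@nSubjectsPerGroup[1], object@nSubjectsPerGroup[2],
    object@durationS, object@fs, object@carrierBand$name))
  cat(sprintf("  baseline H = %.2f, effect H = %.2f on %d planted edge(s)\n",
              object@baselineHurst, object@effectHurst,
              nrow(object@effectEdges)))
})
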