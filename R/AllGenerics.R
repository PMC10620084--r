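#' @rdname accessors
#' @export
setGeneric("spikeCounts", function(x) standardGeneric("spikeCounts"))

#' @rdname accessors
#' @export
setGeneric("binInfo", function(x) standardGeneric("binInfo"))

#' @rdname accessors
#' @export
setGeneric("motionValues", function(x) standardGeneric("motionValues"))

#' @rdname accessors
#' @export
setGeneric("spatialMaps", function(x) standardGeneric("spatialMaps"))

#' @rdname accessors
#' @export
setGeneric("temporalProfiles", function(x) standardGeneric("temporalProfiles"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("designValues", function(x) standardGeneric("designValues"))

#' @rdname accessors
#' @export
setGeneric("columnGroups", function(x) standardGeneric("columnGroups"))

#' @rdname accessors
#' @export
setGeneric("columnMeta", function(x) standardGeneric("columnMeta"))

#' @rdname accessors
#' @export
setGeneric("fittedWeights", function(x, ...) standardGeneric("fittedWeights"))

#' @rdname accessors
#' @export
setGeneric("penalties", function(x) standardGeneric("penalties"))

#' @rdname accessors
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))

#' @rdname accessors
#' @export
setGeneric("veOverall", function(x) standardGeneric("veOverall"))

#' @rdname accessors
#' @export
setGeneric("sessionTruth", function(x) standardGeneric("sessionTruth"))

#' Accessors for movenc classes
#'
#' Small accessor layer so user code never touches slots directly:
#' `spikeCounts()` returns the unit-by-bin count matrix, `binInfo()` the bin
#' annotation of a design or spike container, `motionValues()` the motion
#' energy matrix, `spatialMaps()`/`temporalProfiles()`/`singularValues()` the
#' parts of a [MotionComponents-class] object, `designValues()` the z-scored
#' design, `columnGroups()`/`columnMeta()` its column annotation,
#' `fittedWeights()` (with `denormalize = TRUE` to map back to raw regressor
#' units), `penalties()`, `cvPredictions()` and `veOverall()` the parts of a
#' [FitResult-class], and `sessionTruth()` the ground-truth list of a
#' synthetic session.
#'
#' @param x an object of the documented class.
#' @param ... passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
setMethod("spikeCounts", "BinnedSpikes", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
setMethod("binInfo", "BinnedSpikes", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
setMethod("binInfo", "DesignMatrix", function(x) x@bins)

#' @rdname accessors
setMethod("motionValues", "MotionMatrix", function(x) x@M)

#' @rdname accessors
setMethod("spatialMaps", "MotionComponents", function(x) x@spatial)

#' @rdname accessors
setMethod("temporalProfiles", "MotionComponents", function(x) x@temporal)

#' @rdname accessors
setMethod("singularValues", "MotionComponents", function(x) x@d)

#' @rdname accessors
setMethod("designValues", "DesignMatrix", function(x) x@X)

#' @rdname accessors
setMethod("columnGroups", "DesignMatrix", function(x)
  x@columnMeta$group)

#' @rdname accessors
setMethod("columnMeta", "DesignMatrix", function(x) x@columnMeta)

#' @rdname accessors
setMethod("columnMeta", "FitResult", function(x) x@columnMeta)

#' @param denormalize logical; if `TRUE` divide each weight by the design
#'   column scale recorded at assembly, giving weights per raw regressor unit.
#' @param design the [DesignMatrix-class] the fit was computed on (required
#'   when `denormalize = TRUE`).
#' @rdname accessors
setMethod("fittedWeights", "FitResult",
  function(x, denormalize = FALSE, design = NULL) {
    w <- x@weights
    if (denormalize) {
      if (is.null(design))
        stop("denormalizing weights needs the design matrix")
      w <- w / design@scale
      w[design@zeroVar, ] <- 0
    }
    w
  })

#' @rdname accessors
setMethod("penalties", "FitResult", function(x)
  setNames(x@lambda, x@units))

#' @rdname accessors
setMethod("cvPredictions", "FitResult", function(x) x@predictions)

#' @rdname accessors
setMethod("veOverall", "FitResult", function(x)
  setNames(x@ve, x@units))

#' @rdname accessors
setMethod("sessionTruth", "SyntheticSession", function(x) x@truth)

setMethod("show", "SessionConfig", function(object) {
  p <- object@params
  cat(sprintf("SessionConfig: %s task, %d trials, %d units, bin %.4g s\n",
              p$task, p$nTrials, p$nUnits, p$binWidth))
  cat(sprintf("  latents: %d (AR %.2f), video %dx%d @ %g Hz, seed %d\n",
              p$nLatents, p$latentAr, p$frameHeight, p$frameWidth,
              p$frameRate, p$seed))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack (%s view): %d frames of %dx%d @ %g Hz\n",
              object@view, d[1], d[2], d[3], object@frameRate))
})

setMethod("show", "MotionMatrix", function(object) {
  cat(sprintf("MotionMatrix (%s view): %d ROI pixels x %d frame intervals\n",
              object@view, nrow(object@M), ncol(object@M)))
})

setMethod("show", "MotionComponents", function(object) {
  cat(sprintf("MotionComponents (%s view): %d components over %d pixels\n",
              object@view, ncol(object@spatial), nrow(object@spatial)))
  cat("  singular values: ",
      paste(signif(head(object@d, 5), 3), collapse = ", "),
      if (length(object@d) > 5) ", ..." else "", "\n", sep = "")
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d bins x %d columns (bin %.4g s)\n",
              nrow(object@X), ncol(object@X), object@binWidth))
  tab <- table(object@columnMeta$group)
  cat("  groups: ",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d trials in %d folds (seed %d)\n",
              length(object@trial), object@nFolds, object@seed))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %d units, %d columns\n",
              length(object@units), nrow(object@weights)))
  cat(sprintf("  crossvalidated %%VE: median %.2f [%.2f, %.2f]\n",
              stats::median(object@ve), min(object@ve), max(object@ve)))
})

setMethod("show", "SyntheticSession", function(object) {
  p <- object@config@params
  cat(sprintf("SyntheticSession: %s task, %d trials, %d units, %d bins\n",
              p$task, p$nTrials, p$nUnits, nrow(object@bins)))
  cat(sprintf("  modeled bins: %d; confound gain: %g\n",
              sum(object@bins$modeled), object@truth$confoundGain))
})
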