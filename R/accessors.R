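#' @rdname FluorImage-class
#' @export
setMethod("pixels", "FluorImage", function(x) x@pixels)

#' @rdname FluorImage-class
#' @export
setMethod("pixelSizeNm", "FluorImage", function(x) x@pixelSizeNm)

#' @rdname FluorImage-class
#' @export
setMethod("dim", "FluorImage", function(x) dim(x@pixels))

#' @rdname exFactor
#' @export
setMethod("exFactor", "CalibrationResult", function(x) x@factor)

#' @rdname perExperiment
#' @export
setMethod("perExperiment", "CalibrationResult", function(x) x@perExperiment)

#' @rdname periodNm
#' @export
setMethod("periodNm", "PeriodEstimate", function(x) x@periodNm)

#' @rdname peakPositionsNm
#' @export
setMethod("peakPositionsNm", "PeriodEstimate", function(x) x@peakPositionsNm)

#' @rdname factorApplied
#' @export
setMethod("factorApplied", "PeriodEstimate", function(x) x@factorApplied)

#' @rdname segmentScores
#' @export
setMethod("segmentScores", "AbundanceResult", function(x) x@scores)

#' @rdname mpsAbundance
#' @export
setMethod("mpsAbundance", "AbundanceResult", function(x) x@abundance)

#' @rdname fwhmNm
#' @export
setMethod("fwhmNm", "ResolutionEstimate", function(x) x@fwhmNm)

setMethod("show", "FluorImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FluorImage: %d x %d px at %.4g nm/px (%.3g x %.3g um)\n",
              d[2], d[1], object@pixelSizeNm,
              d[2] * object@pixelSizeNm / 1e3, d[1] * object@pixelSizeNm / 1e3))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult (%s): factor %.4g +/- %.3g (n = %d experiments)\n",
              object@structure, object@factor, object@sd,
              nrow(object@perExperiment)))
})

setMethod("show", "PeriodEstimate", function(object) {
  cat(sprintf("PeriodEstimate: %.4g nm over %d periods (factor applied: %.4g)\n",
              object@periodNm, object@nPeriods, object@factorApplied))
})

setMethod("show", "AbundanceResult", function(object) {
  cat(sprintf(
    "AbundanceResult: %d/%d segments above r = %.3g (abundance %.3f; %d undefined)\n",
    object@nAbove, object@nTotal, object@threshold, object@abundance,
    object@nUndefined))
})

setMethod("show", "ResolutionEstimate", function(object) {
  cat(sprintf("ResolutionEstimate: FWHM %.4g +/- %.3g nm (n = %d, %d failed fits)\n",
              object@fwhmNm, object@sdNm, object@n, object@nFailed))
})

setMethod("show", "AxonGroundTruth", function(object) {
  cat(sprintf(
    "AxonGroundTruth: period %.4g nm, %d centerline points%s, %d rings realized\n",
    object@periodNm, nrow(object@centerline),
    if (object@expanded) sprintf(", expanded x%.3g", object@factorApplied) else "",
    nrow(object@ringCentersNm)))
})
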