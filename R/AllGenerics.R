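#' @rdname FluorImage-class
#' @param object,x a package object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname FluorImage-class
#' @export
setGeneric("pixelSizeNm", function(x) standardGeneric("pixelSizeNm"))

#' Pooled expansion factor of a calibration result
#' @param x a \linkS4class{CalibrationResult}.
#' @export
setGeneric("exFactor", function(x) standardGeneric("exFactor"))

#' Per-experiment factors of a calibration result
#' @param x a \linkS4class{CalibrationResult}.
#' @export
setGeneric("perExperiment", function(x) standardGeneric("perExperiment"))

#' Estimated period in nm
#' @param x a \linkS4class{PeriodEstimate}.
#' @export
setGeneric("periodNm", function(x) standardGeneric("periodNm"))

#' Refined peak positions backing a period estimate
#' @param x a \linkS4class{PeriodEstimate}.
#' @export
setGeneric("peakPositionsNm", function(x) standardGeneric("peakPositionsNm"))

#' Expansion factor already applied to an estimate
#' @param x a \linkS4class{PeriodEstimate}.
#' @export
setGeneric("factorApplied", function(x) standardGeneric("factorApplied"))

#' Per-segment scores of an abundance result
#' @param x an \linkS4class{AbundanceResult}.
#' @export
setGeneric("segmentScores", function(x) standardGeneric("segmentScores"))

#' MPS abundance (proportion of segments above threshold)
#' @param x an \linkS4class{AbundanceResult}.
#' @export
setGeneric("mpsAbundance", function(x) standardGeneric("mpsAbundance"))

#' Mean FWHM of a resolution estimate
#' @param x a \linkS4class{ResolutionEstimate}.
#' @export
setGeneric("fwhmNm", function(x) standardGeneric("fwhmNm"))
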