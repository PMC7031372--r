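#' @import methods
NULL

#' FluorImage: a 2D fluorescence raster with physical pixel size
#'
#' The universal image carrier of the package: a matrix of non-negative
#' intensities (arbitrary photon-count units) together with the physical size
#' of one pixel in nanometres. Rows index y, columns index x; the centre of
#' pixel \code{[i, j]} sits at physical coordinates
#' \code{((j - 0.5) * pixelSizeNm, (i - 0.5) * pixelSizeNm)} with the origin at
#' the image corner.
#'
#' @slot pixels numeric matrix of intensities, all finite and >= 0.
#' @slot pixelSizeNm physical size of one pixel in nm (> 0).
#' @exportClass FluorImage
setClass("FluorImage",
  representation(pixels = "matrix", pixelSizeNm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0)
      msg <- c(msg, "pixelSizeNm must be a single positive number")
    if (!is.numeric(object@pixels) || any(dim(object@pixels) < 1L))
      msg <- c(msg, "pixels must be a numeric matrix with both dimensions >= 1")
    else if (any(!is.finite(object@pixels)) || any(object@pixels < 0))
      msg <- c(msg, "all pixel intensities must be finite and >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FluorImage
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixelSizeNm physical pixel size in nm.
#' @return A \linkS4class{FluorImage}.
#' @examples
#' img <- FluorImage(matrix(0, 8, 8), pixelSizeNm = 100)
#' pixelSizeNm(img)
#' @export
FluorImage <- function(pixels, pixelSizeNm) {
  new("FluorImage", pixels = pixels, pixelSizeNm = as.numeric(pixelSizeNm))
}

#' ImagingSpec: optical and camera model of one acquisition
#'
#' Gaussian point-spread function specified by its lateral full width at half
#' maximum, raster sampling, and a widefield camera noise model: Poisson
#' resampling of the expected counts (shot noise) followed by additive Gaussian
#' read noise, clipped at zero.
#'
#' @slot psfFwhmNm lateral PSF FWHM in nm (> 0).
#' @slot pixelSizeNm raster sampling in nm per pixel (> 0).
#' @slot readNoiseSd Gaussian read-noise SD in counts (>= 0).
#' @slot shotNoise logical; apply Poisson resampling of expected counts.
#' @slot seed integer RNG seed used by the renderer.
#' @exportClass ImagingSpec
setClass("ImagingSpec",
  representation(psfFwhmNm = "numeric", pixelSizeNm = "numeric",
                 readNoiseSd = "numeric", shotNoise = "logical",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@psfFwhmNm <= 0) msg <- c(msg, "psfFwhmNm must be > 0")
    if (object@pixelSizeNm <= 0) msg <- c(msg, "pixelSizeNm must be > 0")
    if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param psfFwhmNm,pixelSizeNm,readNoiseSd,shotNoise,seed see slot docs.
#' @rdname ImagingSpec-class
#' @examples
#' ImagingSpec(psfFwhmNm = 360.51, pixelSizeNm = 100)
#' @export
ImagingSpec <- function(psfFwhmNm, pixelSizeNm = 100, readNoiseSd = 3,
                        shotNoise = TRUE, seed = 1L) {
  new("ImagingSpec", psfFwhmNm = as.numeric(psfFwhmNm),
      pixelSizeNm = as.numeric(pixelSizeNm),
      readNoiseSd = as.numeric(readNoiseSd), shotNoise = as.logical(shotNoise),
      seed = as.integer(seed))
}

#' ExpansionSpec: isotropic physical expansion applied to coordinates
#'
#' @slot factor isotropic linear expansion factor (>= 1 for expanded samples;
#'   1 means no expansion).
#' @slot distortionAmplitude relative amplitude of an optional smooth
#'   non-isotropy field (0 = perfectly isotropic).
#' @exportClass ExpansionSpec
setClass("ExpansionSpec",
  representation(factor = "numeric", distortionAmplitude = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@factor < 1) msg <- c(msg, "expansion factor must be >= 1")
    if (object@distortionAmplitude < 0)
      msg <- c(msg, "distortionAmplitude must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param factor,distortionAmplitude see slot docs.
#' @rdname ExpansionSpec-class
#' @examples
#' ExpansionSpec(factor = 4.68)
#' @export
ExpansionSpec <- function(factor = 1, distortionAmplitude = 0) {
  new("ExpansionSpec", factor = as.numeric(factor),
      distortionAmplitude = as.numeric(distortionAmplitude))
}

#' AxonGroundTruth: planted geometry and labeling of a simulated axon
#'
#' Describes an axon carrying a transverse ring lattice (the MPS): an ordered
#' centerline in nm, the lattice period and phase, the Gaussian axial width and
#' transverse extent of each ring, photon amplitudes, and the degradation
#' parameters (ring dropout and positional jitter) used to emulate cytoskeleton
#' remodeling. After rendering, the object returned alongside the image carries
#' the expanded-space centerline and the realized ring centres.
#'
#' @slot centerline two-column matrix of (x, y) nm coordinates, >= 2 points.
#' @slot periodNm lattice spacing in nm (> 0); the MPS measures ~190 nm.
#' @slot phaseNm arc-length offset of the first ring (nm).
#' @slot ringSigmaNm Gaussian sigma of one ring's axial profile (nm, > 0).
#' @slot axonWidthNm transverse extent of the rings (nm).
#' @slot amplitude expected peak counts per ring element before blur.
#' @slot background expected background counts per pixel.
#' @slot ringDropoutP probability that a ring is unlabeled, in [0, 1].
#' @slot phaseJitterSdNm per-ring positional jitter SD (pre-expansion nm).
#' @slot expanded logical; TRUE once coordinates have been scaled.
#' @slot factorApplied expansion factor applied to the coordinates (1 if none).
#' @slot ringCentersNm realized ring centres (two-column matrix, filled by the
#'   renderer; rows drop out with \code{ringDropoutP}).
#' @slot ringArcNm realized arc-length positions of the rings (filled by the
#'   renderer, same space as \code{centerline}).
#' @exportClass AxonGroundTruth
setClass("AxonGroundTruth",
  representation(centerline = "matrix", periodNm = "numeric",
                 phaseNm = "numeric", ringSigmaNm = "numeric",
                 axonWidthNm = "numeric", amplitude = "numeric",
                 background = "numeric", ringDropoutP = "numeric",
                 phaseJitterSdNm = "numeric", expanded = "logical",
                 factorApplied = "numeric", ringCentersNm = "matrix",
                 ringArcNm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@centerline) != 2L || nrow(object@centerline) < 2L)
      msg <- c(msg, "centerline must be a two-column matrix with >= 2 points")
    if (object@periodNm <= 0) msg <- c(msg, "periodNm must be > 0")
    if (object@ringSigmaNm <= 0) msg <- c(msg, "ringSigmaNm must be > 0")
    if (object@ringDropoutP < 0 || object@ringDropoutP > 1)
      msg <- c(msg, "ringDropoutP must be in [0, 1]")
    if (object@phaseJitterSdNm < 0)
      msg <- c(msg, "phaseJitterSdNm must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param centerline,periodNm,phaseNm,ringSigmaNm,axonWidthNm,amplitude,background,ringDropoutP,phaseJitterSdNm
#'   see slot docs.
#' @rdname AxonGroundTruth-class
#' @examples
#' gt <- AxonGroundTruth(cbind(c(0, 5000), c(500, 500)), periodNm = 190)
#' @export
AxonGroundTruth <- function(centerline, periodNm = 190, phaseNm = periodNm / 2,
                            ringSigmaNm = 15, axonWidthNm = 400,
                            amplitude = 80, background = 10,
                            ringDropoutP = 0, phaseJitterSdNm = 0) {
  new("AxonGroundTruth", centerline = centerline,
      periodNm = as.numeric(periodNm), phaseNm = as.numeric(phaseNm),
      ringSigmaNm = as.numeric(ringSigmaNm),
      axonWidthNm = as.numeric(axonWidthNm), amplitude = as.numeric(amplitude),
      background = as.numeric(background),
      ringDropoutP = as.numeric(ringDropoutP),
      phaseJitterSdNm = as.numeric(phaseJitterSdNm), expanded = FALSE,
      factorApplied = 1,
      ringCentersNm = matrix(numeric(0), 0, 2), ringArcNm = numeric(0))
}

#' PopulationSpec: design of a pre/post measurement population
#'
#' Emulates the calibration measurements: repeated experiments, each measuring
#' a population of object diameters (gel blocks or the microtubule network
#' delineating nuclei) before and after expansion. True lengths are log-normal
#' with coefficient of variation \code{cv}; every measurement is further
#' corrupted by a multiplicative error of coefficient of variation
#' \code{measurementCv}. Pre and post populations are independent draws (the
#' same cell is not remeasured).
#'
#' @slot nExperiments number of experiments (>= 1).
#' @slot nItemsPerExperiment measured items per experiment and stage (>= 1).
#' @slot meanLengthNm mean pre-expansion length (nm).
#' @slot cv coefficient of variation of the true lengths (>= 0).
#' @slot measurementCv coefficient of variation of measurement error (>= 0).
#' @slot seed integer RNG seed.
#' @exportClass PopulationSpec
setClass("PopulationSpec",
  representation(nExperiments = "integer", nItemsPerExperiment = "integer",
                 meanLengthNm = "numeric", cv = "numeric",
                 measurementCv = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nExperiments < 1L) msg <- c(msg, "nExperiments must be >= 1")
    if (object@nItemsPerExperiment < 1L)
      msg <- c(msg, "nItemsPerExperiment must be >= 1")
    if (object@meanLengthNm <= 0) msg <- c(msg, "meanLengthNm must be > 0")
    if (object@cv < 0 || object@measurementCv < 0)
      msg <- c(msg, "cv and measurementCv must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param nExperiments,nItemsPerExperiment,meanLengthNm,cv,measurementCv,seed
#'   see slot docs.
#' @rdname PopulationSpec-class
#' @examples
#' PopulationSpec(6, 40, meanLengthNm = 25000, cv = 0.15, measurementCv = 0.02)
#' @export
PopulationSpec <- function(nExperiments, nItemsPerExperiment, meanLengthNm,
                           cv = 0.15, measurementCv = 0.02, seed = 1L) {
  new("PopulationSpec", nExperiments = as.integer(nExperiments),
      nItemsPerExperiment = as.integer(nItemsPerExperiment),
      meanLengthNm = as.numeric(meanLengthNm), cv = as.numeric(cv),
      measurementCv = as.numeric(measurementCv), seed = as.integer(seed))
}

#' MeasurementPopulation: one measured population of lengths
#'
#' @slot lengthsNm measured lengths in nm, all > 0, non-empty.
#' @slot stage \code{"pre"} or \code{"post"} expansion.
#' @slot structure \code{"gel"} (macroscopic gel block) or
#'   \code{"protein-structure"} (intracellular structure such as the
#'   perinuclear microtubule network).
#' @slot experimentId experiment label.
#' @exportClass MeasurementPopulation
setClass("MeasurementPopulation",
  representation(lengthsNm = "numeric", stage = "character",
                 structure = "character", experimentId = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@lengthsNm) == 0L)
      msg <- c(msg, "population must be non-empty")
    else if (any(!is.finite(object@lengthsNm)) || any(object@lengthsNm <= 0))
      msg <- c(msg, "all lengths must be finite and > 0")
    if (!object@stage %in% c("pre", "post"))
      msg <- c(msg, "stage must be 'pre' or 'post'")
    if (!object@structure %in% c("gel", "protein-structure"))
      msg <- c(msg, "structure must be 'gel' or 'protein-structure'")
    if (is.null(msg)) TRUE else msg
  })

#' @param lengthsNm,stage,structure,experimentId see slot docs.
#' @rdname MeasurementPopulation-class
#' @examples
#' MeasurementPopulation(c(10, 12, 11), "pre", "gel", "exp1")
#' @export
MeasurementPopulation <- function(lengthsNm, stage, structure,
                                  experimentId = "exp1") {
  new("MeasurementPopulation", lengthsNm = as.numeric(lengthsNm),
      stage = stage, structure = structure,
      experimentId = as.character(experimentId))
}

#' CalibrationResult: pooled and per-experiment expansion factors
#'
#' @slot factor pooled expansion factor (unweighted mean over experiments).
#' @slot perExperiment data.frame with columns \code{experiment_id} and
#'   \code{factor}.
#' @slot sd sample SD of the per-experiment factors (0 with a warning when a
#'   single experiment is pooled).
#' @slot structure \code{"gel"} or \code{"protein-structure"}.
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(factor = "numeric", perExperiment = "data.frame",
                 sd = "numeric", structure = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@factor <= 0) msg <- c(msg, "factor must be > 0")
    if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
    if (nrow(object@perExperiment) < 1L)
      msg <- c(msg, "perExperiment must be non-empty")
    if (is.null(msg)) TRUE else msg
  })

#' Profile1D: an intensity profile along a traced line
#'
#' @slot positionsNm strictly increasing arc-length sample positions (nm).
#' @slot intensities matched intensity values, all finite.
#' @slot source free-text provenance (image id and polyline).
#' @exportClass Profile1D
setClass("Profile1D",
  representation(positionsNm = "numeric", intensities = "numeric",
                 source = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@positionsNm) < 5L)
      msg <- c(msg, "profile must have at least 5 samples")
    if (length(object@positionsNm) != length(object@intensities))
      msg <- c(msg, "positions and intensities must have equal length")
    if (any(diff(object@positionsNm) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
    if (any(!is.finite(object@intensities)))
      msg <- c(msg, "intensities must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' @param positionsNm,intensities,source see slot docs.
#' @rdname Profile1D-class
#' @examples
#' Profile1D(seq(0, 400, by = 100), c(1, 0, 1, 0, 1))
#' @export
Profile1D <- function(positionsNm, intensities, source = "profile") {
  new("Profile1D", positionsNm = as.numeric(positionsNm),
      intensities = as.numeric(intensities), source = source)
}

#' PeriodEstimate: a single five-peak period measurement
#'
#' The field's standard period measurement: the distance from the first to the
#' fifth consecutive intensity peak, divided by four. \code{factorApplied}
#' records the expansion factor by which the raw (expanded-space) value was
#' divided; 1 means the estimate is still in acquisition-space nm.
#'
#' @slot periodNm estimated spacing in nm (> 0).
#' @slot nPeriods number of periods spanned by the peak window (default 4).
#' @slot factorApplied expansion factor used for rescaling (1 if none).
#' @slot peakPositionsNm the refined peak positions used, length
#'   \code{nPeriods + 1}, in the same space as \code{periodNm}.
#' @exportClass PeriodEstimate
setClass("PeriodEstimate",
  representation(periodNm = "numeric", nPeriods = "integer",
                 factorApplied = "numeric", peakPositionsNm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@periodNm <= 0) msg <- c(msg, "periodNm must be > 0")
    if (object@nPeriods < 1L) msg <- c(msg, "nPeriods must be >= 1")
    if (length(object@peakPositionsNm) != object@nPeriods + 1L)
      msg <- c(msg, "peakPositionsNm must have nPeriods + 1 entries")
    if (is.null(msg)) TRUE else msg
  })

#' MpsTemplate: the modeled periodic pattern used for regularity scoring
#'
#' A square raster of transverse Gaussian stripes at the modeled MPS spacing,
#' constant along the transverse axis and zero-mean, against which axonal
#' segments are correlated.
#'
#' @slot periodNm modeled spacing in nm (default 190, the consensus MPS
#'   period).
#' @slot stripeSigmaNm Gaussian sigma of one stripe (nm); default matches the
#'   effective imaging resolution.
#' @slot sizeNm square side in nm (default 1000); must cover >= 2 periods.
#' @slot pixelSizeNm raster step in nm.
#' @exportClass MpsTemplate
setClass("MpsTemplate",
  representation(periodNm = "numeric", stripeSigmaNm = "numeric",
                 sizeNm = "numeric", pixelSizeNm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@periodNm, object@stripeSigmaNm, object@sizeNm,
              object@pixelSizeNm) <= 0))
      msg <- c(msg, "all template lengths must be > 0")
    if (object@sizeNm < 2 * object@periodNm)
      msg <- c(msg, "template size must cover at least 2 full periods")
    if (is.null(msg)) TRUE else msg
  })

#' @param periodNm,stripeSigmaNm,sizeNm,pixelSizeNm see slot docs.
#' @rdname MpsTemplate-class
#' @examples
#' MpsTemplate(periodNm = 190, stripeSigmaNm = 33, sizeNm = 1000,
#'             pixelSizeNm = 20)
#' @export
MpsTemplate <- function(periodNm = 190, stripeSigmaNm = 33, sizeNm = 1000,
                        pixelSizeNm = 20) {
  new("MpsTemplate", periodNm = as.numeric(periodNm),
      stripeSigmaNm = as.numeric(stripeSigmaNm), sizeNm = as.numeric(sizeNm),
      pixelSizeNm = as.numeric(pixelSizeNm))
}

#' AbundanceResult: per-segment correlation scores and MPS abundance
#'
#' @slot scores data.frame of per-segment scores with columns \code{x_nm},
#'   \code{y_nm} (segment origin), \code{correlation}, \code{phase_shift_nm}
#'   and \code{defined} (FALSE for zero-variance segments, which are excluded
#'   from the abundance denominator).
#' @slot threshold correlation cutoff (default 0.12).
#' @slot abundance proportion of defined segments strictly above threshold.
#' @slot nTotal number of defined segments.
#' @slot nAbove number of defined segments above threshold.
#' @slot nUndefined number of zero-variance segments excluded.
#' @exportClass AbundanceResult
setClass("AbundanceResult",
  representation(scores = "data.frame", threshold = "numeric",
                 abundance = "numeric", nTotal = "integer",
                 nAbove = "integer", nUndefined = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nTotal < 1L) msg <- c(msg, "nTotal must be >= 1")
    if (abs(object@abundance - object@nAbove / object@nTotal) > 1e-12)
      msg <- c(msg, "abundance must equal nAbove / nTotal")
    if (is.null(msg)) TRUE else msg
  })

#' ResolutionEstimate: lateral resolution as mean bead-image FWHM
#'
#' @slot fwhmNm mean FWHM over successfully fitted emitters (nm).
#' @slot sdNm sample SD over emitters (nm).
#' @slot n number of emitters used.
#' @slot perEmitter data.frame with columns \code{x_nm}, \code{y_nm},
#'   \code{fwhm_nm}.
#' @slot nFailed number of emitters whose fit failed (excluded).
#' @exportClass ResolutionEstimate
setClass("ResolutionEstimate",
  representation(fwhmNm = "numeric", sdNm = "numeric", n = "integer",
                 perEmitter = "data.frame", nFailed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@fwhmNm <= 0) msg <- c(msg, "fwhmNm must be > 0")
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (object@sdNm < 0) msg <- c(msg, "sdNm must be >= 0")
    if (is.null(msg)) TRUE else msg
  })
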