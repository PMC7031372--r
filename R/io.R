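# TIFF / CSV / JSON interchange. Images travel as single-channel 16-bit
# grayscale TIFF with a sidecar JSON carrying the physical pixel size and
# the intensity scale (baseline TIFF cannot carry either, and the tiff
# writer exposes no resolution tags). The reader also understands
# ImageJ-convention description strings on TIFFs produced elsewhere.

#' Write a FluorImage as a 16-bit grayscale TIFF
#'
#' Intensities are scaled to the 16-bit range by \code{max(pixels)}; the
#' scale factor and the pixel size in nm are recorded in a sidecar JSON
#' (\code{<path>.json}) that \code{\link{readImageTiff}} uses to restore the
#' original values.
#'
#' @param image a \linkS4class{FluorImage}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeImageTiff <- function(image, path) {
  stopifnot(is(image, "FluorImage"))
  m <- pixels(image)
  scale <- max(m, 1e-12)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  meta <- list(pixel_size_nm = pixelSizeNm(image), intensity_scale = scale,
               width_px = ncol(m), height_px = nrow(m))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a FluorImage written by writeImageTiff
#'
#' Pixel size and intensity scale are recovered from the sidecar JSON when
#' present, else from the ImageJ description string; a bare TIFF without
#' either is an error because physical calibration is mandatory.
#'
#' @param path TIFF path.
#' @return A \linkS4class{FluorImage}.
#' @export
readImageTiff <- function(path) {
  m <- tiff::readTIFF(path, info = TRUE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    px <- meta$pixel_size_nm
    scale <- meta$intensity_scale
  } else {
    desc <- attr(m, "description")
    xres <- attr(m, "x.resolution")
    px <- NA_real_
    scale <- 1
    if (!is.null(desc) && grepl("pixelsize=", desc)) {
      px <- as.numeric(sub(".*pixelsize=([0-9.eE+-]+).*", "\\1", desc))
    } else if (!is.null(xres) && xres > 0) {
      unit <- attr(m, "resolution.unit")
      perNm <- switch(if (is.null(unit)) "inch" else unit,
                      cm = 1e7, inch = 2.54e7, 1e7)
      px <- perNm / xres
    }
    if (!is.finite(px)) stop("no pixel-size metadata found for ", path)
  }
  if (!is.finite(px) || px <= 0) stop("invalid pixel size metadata in ", path)
  FluorImage(unclass(m)[, , drop = TRUE] * scale, pixelSizeNm = px)
}

#' Write ground truth as sidecar JSON
#'
#' @param gt an \linkS4class{AxonGroundTruth}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruthJson <- function(gt, path) {
  stopifnot(is(gt, "AxonGroundTruth"))
  obj <- list(
    centerline_nm = unname(apply(gt@centerline, 1, as.numeric, simplify = FALSE)),
    period_nm = gt@periodNm, phase_nm = gt@phaseNm,
    ring_sigma_nm = gt@ringSigmaNm, axon_width_nm = gt@axonWidthNm,
    amplitude = gt@amplitude, background = gt@background,
    ring_dropout_p = gt@ringDropoutP, phase_jitter_sd_nm = gt@phaseJitterSdNm,
    expanded = gt@expanded, factor_applied = gt@factorApplied,
    ring_arc_nm = gt@ringArcNm,
    ring_centers_nm = unname(apply(gt@ringCentersNm, 1, as.numeric,
                                   simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a measurement-population table as CSV
#'
#' Columns: \code{experiment_id}, \code{item_id}, \code{stage} (pre|post),
#' \code{length_nm} — the interchange format the calibration module reads.
#'
#' @param table data.frame as returned by \code{\link{samplePopulation}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePopulationCsv <- function(table, path) {
  need <- c("experiment_id", "item_id", "stage", "length_nm")
  stopifnot(all(need %in% names(table)))
  utils::write.csv(table[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement-population table from CSV
#'
#' @param path CSV path with columns as written by
#'   \code{\link{writePopulationCsv}}.
#' @return data.frame.
#' @export
readPopulationCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment_id", "item_id", "stage", "length_nm")
  if (!all(need %in% names(df)))
    stop("population CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' Read a polyline from JSON
#'
#' The JSON is a list of [x, y] nm coordinate pairs, the sidecar format used
#' for traced axon centerlines.
#'
#' @param path JSON path.
#' @return two-column numeric matrix.
#' @export
readPolylineJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- if (is.matrix(obj)) obj else do.call(rbind, obj)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("polyline JSON must contain [x, y] pairs")
  m
}

#' Write a polyline as JSON
#' @param pts two-column matrix of nm coordinates.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePolylineJson <- function(pts, path) {
  jsonlite::write_json(unname(apply(pts, 1, as.numeric, simplify = FALSE)),
                       path, digits = NA)
  invisible(path)
}
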