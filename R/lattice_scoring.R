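# Correlation-based regularity scoring: tile an axon into 1 um x 1 um
# segments (in pre-expansion dimensions), correlate each against a modeled
# periodic stripe pattern with a phase search, and summarize the proportion
# of segments whose correlation exceeds a threshold (MPS abundance).

#' Rasterize the modeled MPS template
#'
#' A square raster of transverse Gaussian stripes at the modeled spacing,
#' constant across the transverse axis and shifted to zero mean. For
#' expanded-space segments the template is stretched by the expansion factor
#' rather than shrinking the data, avoiding a second resampling of the
#' image.
#'
#' @param spec an \linkS4class{MpsTemplate} (pre-expansion nm).
#' @param phaseNm axial offset of the first stripe, acquisition-space nm.
#' @param factor expansion factor by which to stretch the template (default 1).
#' @param dims optional c(nrow, ncol) raster dimensions to match a segment
#'   exactly; default derived from \code{sizeNm * factor / pixelSizeNm}.
#' @return A zero-mean numeric matrix (rows = transverse, columns = axial).
#'   A plain matrix, not a \linkS4class{FluorImage}: the template is a
#'   correlation kernel, and the non-negativity invariant of imaging rasters
#'   deliberately does not apply to it.
#' @examples
#' tpl <- buildTemplate(MpsTemplate(pixelSizeNm = 20))
#' dim(tpl)
#' @export
buildTemplate <- function(spec, phaseNm = 0, factor = 1, dims = NULL) {
  stopifnot(is(spec, "MpsTemplate"))
  px <- spec@pixelSizeNm
  period <- spec@periodNm * factor
  sigma <- spec@stripeSigmaNm * factor
  if (is.null(dims)) {
    n <- max(2L, round(spec@sizeNm * factor / px))
    dims <- c(n, n)
  }
  x <- (seq_len(dims[2]) - 0.5) * px
  kmin <- floor((min(x) - 4 * sigma - phaseNm) / period)
  kmax <- ceiling((max(x) + 4 * sigma - phaseNm) / period)
  prof <- rep(0, length(x))
  for (k in kmin:kmax)
    prof <- prof + exp(-(x - phaseNm - k * period)^2 / (2 * sigma^2))
  prof <- prof - mean(prof)
  matrix(prof, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

#' Tile an axon into square segments along its centerline
#'
#' Cuts consecutive, non-overlapping square segments along the arc length of
#' the centerline and resamples each by bilinear interpolation so the local
#' axon tangent is the horizontal (column) axis — curvature is straightened,
#' which is what makes a single axial template applicable to curved axons.
#'
#' @param image a \linkS4class{FluorImage} (acquisition space).
#' @param centerline two-column matrix of nm waypoints.
#' @param sizeNm segment side in pre-expansion nm (default 1000).
#' @param factor expansion factor of the acquisition (segment side in
#'   acquisition space is \code{sizeNm * factor}).
#' @return list with \code{segments} (list of \linkS4class{FluorImage}),
#'   \code{origins} (n x 2 matrix, acquisition-space nm of each segment's
#'   starting point on the centerline) and \code{nSkipped} (segments dropped
#'   because they left the image; each emits a warning).
#' @examples
#' gt <- AxonGroundTruth(cbind(c(2000, 6000), c(1500, 1500)))
#' ren <- renderAxon(gt, ImagingSpec(90, 20, shotNoise = FALSE,
#'                                   readNoiseSd = 0))
#' tiles <- tileAxon(ren$image, ren$groundTruth@centerline)
#' length(tiles$segments)
#' @export
tileAxon <- function(image, centerline, sizeNm = 1000, factor = 1) {
  stopifnot(is(image, "FluorImage"))
  L <- sizeNm * factor
  total <- polyArcLength(centerline)[nrow(centerline)]
  nseg <- floor(total / L)
  if (nseg < 1L)
    stop(sprintf("axon shorter than one segment (%.0f nm < %.0f nm)",
                 total, L))
  px <- pixelSizeNm(image)
  n <- max(2L, round(L / px))
  segs <- list(); origins <- NULL; skipped <- 0L
  for (k in seq_len(nseg)) {
    s0 <- (k - 1) * L
    tpos <- s0 + (seq_len(n) - 0.5) * px
    at <- polyPointAt(centerline, tpos)
    nrml <- cbind(-at$tangent[, 2], at$tangent[, 1])
    offs <- (seq_len(n) - 0.5) * px - L / 2
    vals <- matrix(NA_real_, n, n)
    for (i in seq_len(n))
      vals[i, ] <- bilinearSample(image,
                                  at$point[, 1] + offs[i] * nrml[, 1],
                                  at$point[, 2] + offs[i] * nrml[, 2])
    if (anyNA(vals)) {
      warning(sprintf("segment %d extends beyond the image; skipped", k))
      skipped <- skipped + 1L
      next
    }
    segs[[length(segs) + 1L]] <- FluorImage(vals, pixelSizeNm = px)
    origins <- rbind(origins, polyPointAt(centerline, s0)$point)
  }
  list(segments = segs, origins = origins, nSkipped = skipped)
}

#' Score one segment against the modeled MPS template
#'
#' Pearson correlation over all pixels between the segment and the template,
#' maximized over axial phase shifts of the template in one-pixel steps
#' across one full period; the maximizing shift is recorded. A segment with
#' zero intensity variance has no defined correlation and is flagged.
#'
#' @param segment a \linkS4class{FluorImage} as produced by
#'   \code{\link{tileAxon}} (axon axis horizontal).
#' @param spec an \linkS4class{MpsTemplate} with
#'   \code{pixelSizeNm == pixelSizeNm(segment)}.
#' @param factor expansion factor used to stretch the template.
#' @return list with \code{correlation}, \code{phaseShiftNm} (in
#'   \code{[0, periodNm * factor)}) and \code{defined}.
#' @examples
#' spec <- MpsTemplate(pixelSizeNm = 20)
#' seg <- FluorImage(buildTemplate(spec) + 10, 20)
#' scoreSegment(seg, spec)$correlation  # 1
#' @export
scoreSegment <- function(segment, spec, factor = 1) {
  stopifnot(is(segment, "FluorImage"), is(spec, "MpsTemplate"))
  if (abs(pixelSizeNm(segment) - spec@pixelSizeNm) > 1e-9)
    stop("segment and template must share one pixel size")
  m <- pixels(segment)
  if (stats::sd(m) == 0)
    return(list(correlation = NA_real_, phaseShiftNm = NA_real_,
                defined = FALSE))
  px <- spec@pixelSizeNm
  nShift <- max(1L, round(spec@periodNm * factor / px))
  best <- -Inf; bestShift <- 0
  v <- as.vector(m)
  for (s in seq_len(nShift) - 1L) {
    tpl <- buildTemplate(spec, phaseNm = s * px, factor = factor,
                         dims = dim(m))
    r <- stats::cor(v, as.vector(tpl))
    if (r > best) { best <- r; bestShift <- s * px }
  }
  list(correlation = best, phaseShiftNm = bestShift, defined = TRUE)
}

#' Score all segments of a tiling
#'
#' @param tiles result of \code{\link{tileAxon}}.
#' @param spec an \linkS4class{MpsTemplate}.
#' @param factor expansion factor used to stretch the template.
#' @return data.frame with columns \code{x_nm}, \code{y_nm},
#'   \code{correlation}, \code{phase_shift_nm}, \code{defined}.
#' @export
scoreSegments <- function(tiles, spec, factor = 1) {
  rows <- lapply(seq_along(tiles$segments), function(k) {
    sc <- scoreSegment(tiles$segments[[k]], spec, factor)
    data.frame(x_nm = tiles$origins[k, 1], y_nm = tiles$origins[k, 2],
               correlation = sc$correlation,
               phase_shift_nm = sc$phaseShiftNm, defined = sc$defined)
  })
  if (!length(rows))
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      correlation = numeric(0), phase_shift_nm = numeric(0),
                      defined = logical(0)))
  do.call(rbind, rows)
}

#' MPS abundance from segment scores
#'
#' The proportion of defined segment correlations strictly above the
#' threshold (default 0.12, the correlation that corresponds to a visibly
#' periodic segment). Zero-variance segments are excluded from the
#' denominator and counted separately.
#'
#' @param scores data.frame as returned by \code{\link{scoreSegments}}, or a
#'   numeric vector of correlations.
#' @param threshold correlation cutoff (default 0.12).
#' @return An \linkS4class{AbundanceResult}.
#' @examples
#' mpsAbundance(abundanceResult(c(0.5, 0.05, 0.3, 0.11)))  # 0.5
#' @export
abundanceResult <- function(scores, threshold = 0.12) {
  if (is.numeric(scores))
    scores <- data.frame(x_nm = NA_real_, y_nm = NA_real_,
                         correlation = scores, phase_shift_nm = NA_real_,
                         defined = !is.na(scores))
  def <- scores$defined & !is.na(scores$correlation)
  nTotal <- sum(def)
  if (nTotal < 1L) stop("all segment scores are undefined")
  nAbove <- sum(scores$correlation[def] > threshold)
  new("AbundanceResult", scores = scores, threshold = threshold,
      abundance = nAbove / nTotal, nTotal = as.integer(nTotal),
      nAbove = as.integer(nAbove), nUndefined = as.integer(sum(!def)))
}

#' Write a histogram of segment correlations as CSV
#'
#' Bins the defined correlation values (default bin width 0.05 over [-1, 1])
#' and writes columns \code{bin_low}, \code{bin_high}, \code{count} — the
#' export format used to compare score distributions across imaging
#' modalities.
#'
#' @param scores data.frame as from \code{\link{scoreSegments}} or numeric
#'   vector of correlations.
#' @param path output CSV path.
#' @param breaks histogram breaks (default \code{seq(-1, 1, by = 0.05)}).
#' @return \code{path}, invisibly.
#' @export
writeScoreHistogramCsv <- function(scores, path,
                                   breaks = seq(-1, 1, by = 0.05)) {
  r <- if (is.numeric(scores)) scores else
    scores$correlation[scores$defined & !is.na(scores$correlation)]
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  utils::write.csv(data.frame(bin_low = utils::head(h$breaks, -1),
                              bin_high = h$breaks[-1], count = h$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
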