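# Synthetic-image generator: axons carrying a planted MPS ring lattice,
# sub-diffraction bead fields, and pre/post measurement populations.
#
# All optics are analytic: a Gaussian ring profile convolved with the
# Gaussian PSF is again a Gaussian (variances add), and a hard-edged
# transverse segment convolved with the PSF is a difference of error
# functions, so the expected image is evaluated in closed form at every
# pixel centre with no gridded convolution error. Noise (Poisson shot +
# Gaussian read, clipped at zero) is applied last.

# Apply the camera noise model to an expected-counts raster.
applyNoise <- function(expected, imaging, seed) {
  out <- expected
  localSeed(seed, {
    if (imaging@shotNoise)
      out <- matrix(stats::rpois(length(out), lambda = out), nrow(out))
    if (imaging@readNoiseSd > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, imaging@readNoiseSd),
                          nrow(out))
  })
  pmax(out, 0)
}

# Optional smooth non-isotropy field: a sinusoidal relative modulation of the
# linear map with wavelength equal to the pattern extent.
expandCoords <- function(pts, expansion) {
  f <- expansion@factor
  out <- pts * f
  a <- expansion@distortionAmplitude
  if (a > 0) {
    span <- max(apply(pts, 2, function(v) diff(range(v))), 1)
    out[, 1] <- out[, 1] * (1 + a * sin(2 * pi * pts[, 2] / span))
    out[, 2] <- out[, 2] * (1 + a * sin(2 * pi * pts[, 1] / span))
  }
  out
}

#' Render a simulated axon with a planted MPS ring lattice
#'
#' Places rings at arc-length positions \code{phaseNm + k * periodNm} along
#' the centerline (optionally jittered and dropped out), scales all
#' coordinates by the expansion factor, draws each surviving ring as a
#' Gaussian-profiled transverse line element convolved with the Gaussian PSF,
#' adds background, and applies shot and read noise. The returned ground
#' truth carries expanded-space coordinates and the realized ring centres.
#'
#' Ring dropout and positional jitter are drawn in pre-expansion space and
#' then scaled, so two renders differing only in expansion factor (same seed)
#' plant rings at exactly proportional coordinates.
#'
#' @param gt an \linkS4class{AxonGroundTruth} (pre-expansion coordinates).
#' @param imaging an \linkS4class{ImagingSpec}.
#' @param expansion an \linkS4class{ExpansionSpec}.
#' @param fovNm optional c(width, height) field of view in nm. When NULL the
#'   field is sized to the expanded centerline plus a margin of three PSF
#'   FWHM plus the transverse ring extent; when given, a centerline whose
#'   margin-padded extent exceeds it is an error.
#' @return list with elements \code{image} (\linkS4class{FluorImage}) and
#'   \code{groundTruth} (expanded-space \linkS4class{AxonGroundTruth}).
#' @examples
#' gt <- AxonGroundTruth(cbind(c(1500, 6500), c(1000, 1000)), periodNm = 190)
#' ren <- renderAxon(gt, ImagingSpec(psfFwhmNm = 90, pixelSizeNm = 20,
#'                                   shotNoise = FALSE, readNoiseSd = 0),
#'                   ExpansionSpec(1))
#' ren$image
#' @export
renderAxon <- function(gt, imaging, expansion = ExpansionSpec(1),
                       fovNm = NULL) {
  stopifnot(is(gt, "AxonGroundTruth"), is(imaging, "ImagingSpec"),
            is(expansion, "ExpansionSpec"))
  f <- expansion@factor
  clExp <- expandCoords(gt@centerline, expansion)

  # ring positions in pre-expansion arc length, so the RNG draws are
  # identical across expansion factors under the same seed
  totalPre <- polyArcLength(gt@centerline)[nrow(gt@centerline)]
  k <- seq(0, floor(max(0, (totalPre - gt@phaseNm)) / gt@periodNm))
  arcPre <- gt@phaseNm + k * gt@periodNm
  arcPre <- arcPre[arcPre <= totalPre]
  if (length(arcPre) == 0L) stop("no ring fits on the centerline")
  keep <- localSeed(childSeed(imaging@seed, 1L),
                    stats::runif(length(arcPre)) >= gt@ringDropoutP)
  jit <- localSeed(childSeed(imaging@seed, 2L),
                   stats::rnorm(length(arcPre), 0, max(gt@phaseJitterSdNm,
                                                       1e-12)))
  if (gt@phaseJitterSdNm == 0) jit <- jit * 0
  arcPre <- pmin(pmax(arcPre + jit, 0), totalPre)[keep]

  arcExp <- arcPre * f
  at <- polyPointAt(clExp, arcExp)
  centers <- at$point
  tangents <- at$tangent

  sigPsf <- fwhmToSigma(imaging@psfFwhmNm)
  sigAx <- gt@ringSigmaNm * f
  sigEff <- sqrt(sigAx^2 + sigPsf^2)
  halfW <- gt@axonWidthNm * f / 2
  margin <- 3 * imaging@psfFwhmNm + halfW

  px <- imaging@pixelSizeNm
  ext <- apply(clExp, 2, range)
  if (is.null(fovNm)) {
    if (any(ext[1, ] - margin < 0))
      stop(sprintf(
        "centerline too close to the origin: extent [%.0f, %.0f] x [%.0f, %.0f] nm needs a %.0f nm margin",
        ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], margin))
    # mirror the origin-side clearance so margins are symmetric
    fovNm <- c(ext[2, 1] + ext[1, 1], ext[2, 2] + ext[1, 2])
  } else if (any(ext[1, ] - margin < 0) || ext[2, 1] + margin > fovNm[1] ||
             ext[2, 2] + margin > fovNm[2]) {
    stop(sprintf(
      "centerline extent [%.0f, %.0f] x [%.0f, %.0f] nm (+%.0f nm margin) exceeds the %0.f x %.0f nm field of view",
      ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], margin, fovNm[1], fovNm[2]))
  }
  nc <- max(2L, ceiling(fovNm[1] / px))
  nr <- max(2L, ceiling(fovNm[2] / px))
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px

  # peak rescaling keeps the ring's integrated signal invariant under blur
  peak <- gt@amplitude * sigAx / sigEff
  expected <- matrix(gt@background, nr, nc)
  axHW <- 5 * sigEff
  trHW <- halfW + 5 * sigPsf
  boxHW <- sqrt(axHW^2 + trHW^2)
  s2psf <- sqrt(2) * sigPsf
  for (r in seq_len(nrow(centers))) {
    cx <- centers[r, 1]; cy <- centers[r, 2]
    tx <- tangents[r, 1]; ty <- tangents[r, 2]
    jr <- which(xc >= cx - boxHW & xc <= cx + boxHW)
    ir <- which(yc >= cy - boxHW & yc <= cy + boxHW)
    if (!length(jr) || !length(ir)) next
    dx <- outer(rep(1, length(ir)), xc[jr] - cx)
    dy <- outer(yc[ir] - cy, rep(1, length(jr)))
    u <- dx * tx + dy * ty          # axial offset
    v <- -dx * ty + dy * tx         # transverse offset
    prof <- exp(-u^2 / (2 * sigEff^2)) *
      0.5 * (erf((halfW - v) / s2psf) + erf((halfW + v) / s2psf))
    expected[ir, jr] <- expected[ir, jr] + peak * prof
  }

  img <- FluorImage(applyNoise(expected, imaging, childSeed(imaging@seed, 3L)),
                    pixelSizeNm = px)
  gtOut <- gt
  gtOut@centerline <- clExp
  gtOut@expanded <- f != 1 || expansion@distortionAmplitude > 0
  gtOut@factorApplied <- f
  gtOut@ringCentersNm <- centers
  gtOut@ringArcNm <- arcExp
  list(image = img, groundTruth = gtOut)
}

#' Render a degraded axon (cytoskeleton-remodeling surrogate)
#'
#' Identical to \code{\link{renderAxon}}; exists as a named entry point for
#' the degradation scenario in which \code{ringDropoutP} and/or
#' \code{phaseJitterSdNm} are positive, emulating the loss and disordering of
#' rings seen after trophic-factor withdrawal. With both parameters at zero
#' the output is identical to \code{renderAxon} under the same seed.
#'
#' @inheritParams renderAxon
#' @return as \code{\link{renderAxon}}.
#' @export
renderDegradedAxon <- function(gt, imaging, expansion = ExpansionSpec(1),
                               fovNm = NULL) {
  renderAxon(gt, imaging, expansion, fovNm)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Render a field of well-separated sub-diffraction beads
#'
#' Beads are uniform disks of the given diameter convolved with the Gaussian
#' PSF (evaluated by equal-area quadrature over the disk), placed on a
#' jittered grid that guarantees at least five PSF FWHM between any two
#' beads, plus noise. The true sub-pixel centres are returned for
#' ground-truth comparison.
#'
#' @param nBeads number of beads (>= 1).
#' @param imaging an \linkS4class{ImagingSpec}.
#' @param beadDiameterNm physical bead diameter in nm (default 20).
#' @param amplitude expected peak counts of one bead image.
#' @param background expected background counts per pixel.
#' @param fovNm optional c(width, height) nm; error if too small to hold the
#'   separation-respecting grid.
#' @return list with \code{image} (\linkS4class{FluorImage}) and
#'   \code{centers} (nBeads x 2 matrix of true centres, nm).
#' @examples
#' bf <- renderBeadField(4, ImagingSpec(psfFwhmNm = 360.51, pixelSizeNm = 100,
#'                                      shotNoise = FALSE, readNoiseSd = 0))
#' bf$image
#' @export
renderBeadField <- function(nBeads, imaging, beadDiameterNm = 20,
                            amplitude = 200, background = 5, fovNm = NULL) {
  stopifnot(is(imaging, "ImagingSpec"))
  if (nBeads < 1) stop("at least one bead must be requested")
  fw <- imaging@psfFwhmNm
  spacing <- 6 * fw
  margin <- 2 * fw
  ncol_ <- ceiling(sqrt(nBeads))
  nrow_ <- ceiling(nBeads / ncol_)
  need <- c(ncol_, nrow_) * spacing + 2 * margin
  if (is.null(fovNm)) {
    fovNm <- need
  } else if (any(fovNm < need)) {
    stop(sprintf(
      "field of view %.0f x %.0f nm too small for %d beads at >= 5 FWHM separation (need %.0f x %.0f nm)",
      fovNm[1], fovNm[2], nBeads, need[1], need[2]))
  }
  gx <- margin + spacing * (seq_len(ncol_) - 0.5)
  gy <- margin + spacing * (seq_len(nrow_) - 0.5)
  grid <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(nBeads), , drop = FALSE]
  centers <- localSeed(childSeed(imaging@seed, 11L),
                       grid + matrix(stats::runif(2 * nBeads, -fw / 2, fw / 2),
                                     ncol = 2))

  px <- imaging@pixelSizeNm
  nc <- ceiling(fovNm[1] / px)
  nr <- ceiling(fovNm[2] / px)
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px
  sig <- fwhmToSigma(fw)

  # equal-area quadrature points over the bead disk
  R <- beadDiameterNm / 2
  nrings <- 4L; nang <- 8L
  rj <- R * sqrt((seq_len(nrings) - 0.5) / nrings)
  th <- 2 * pi * (seq_len(nang) - 1) / nang
  qp <- cbind(c(0, as.vector(outer(rj, th, function(r, a) r * cos(a)))),
              c(0, as.vector(outer(rj, th, function(r, a) r * sin(a)))))

  expected <- matrix(background, nr, nc)
  winHW <- 5 * sig + R
  for (b in seq_len(nBeads)) {
    cx <- centers[b, 1]; cy <- centers[b, 2]
    jr <- which(xc >= cx - winHW & xc <= cx + winHW)
    ir <- which(yc >= cy - winHW & yc <= cy + winHW)
    acc <- matrix(0, length(ir), length(jr))
    for (q in seq_len(nrow(qp))) {
      dx2 <- (xc[jr] - cx - qp[q, 1])^2
      dy2 <- (yc[ir] - cy - qp[q, 2])^2
      acc <- acc + exp(-outer(dy2, dx2, "+") / (2 * sig^2))
    }
    expected[ir, jr] <- expected[ir, jr] + amplitude * acc / nrow(qp)
  }
  img <- FluorImage(applyNoise(expected, imaging, childSeed(imaging@seed, 13L)),
                    pixelSizeNm = px)
  list(image = img, centers = centers)
}

#' Simulate paired pre/post-expansion measurement populations
#'
#' True object lengths are log-normal with mean \code{meanLengthNm} and
#' coefficient of variation \code{cv}; pre- and post-expansion populations
#' are independent draws (the same object is not remeasured), post-expansion
#' truths are multiplied by the expansion factor, and every measurement
#' carries an independent multiplicative log-normal error of coefficient of
#' variation \code{measurementCv}.
#'
#' @param spec a \linkS4class{PopulationSpec}.
#' @param expansion an \linkS4class{ExpansionSpec}.
#' @return data.frame with columns \code{experiment_id}, \code{item_id},
#'   \code{stage} (pre|post) and \code{length_nm}.
#' @examples
#' tab <- samplePopulation(PopulationSpec(2, 5, 25000), ExpansionSpec(4))
#' head(tab)
#' @export
samplePopulation <- function(spec, expansion = ExpansionSpec(1)) {
  stopifnot(is(spec, "PopulationSpec"), is(expansion, "ExpansionSpec"))
  f <- expansion@factor
  s2 <- log(1 + spec@cv^2)
  mu <- log(spec@meanLengthNm) - s2 / 2
  m2 <- log(1 + spec@measurementCv^2)
  drawStage <- function(seed, scale) {
    localSeed(seed, {
      true <- stats::rlnorm(spec@nItemsPerExperiment, mu, sqrt(s2)) * scale
      err <- if (spec@measurementCv > 0)
        stats::rlnorm(spec@nItemsPerExperiment, -m2 / 2, sqrt(m2)) else 1
      true * err
    })
  }
  rows <- lapply(seq_len(spec@nExperiments), function(e) {
    pre <- drawStage(childSeed(spec@seed, 2L * e), 1)
    post <- drawStage(childSeed(spec@seed, 2L * e + 1L), f)
    data.frame(
      experiment_id = sprintf("exp%02d", e),
      item_id = rep(seq_len(spec@nItemsPerExperiment), 2),
      stage = rep(c("pre", "post"), each = spec@nItemsPerExperiment),
      length_nm = c(pre, post))
  })
  do.call(rbind, rows)
}

#' Split a population table into MeasurementPopulation objects
#'
#' @param table data.frame as returned by \code{\link{samplePopulation}} or
#'   \code{\link{readPopulationCsv}}.
#' @param structure \code{"gel"} or \code{"protein-structure"} label to
#'   attach.
#' @return named list (by experiment id) of lists with elements \code{pre}
#'   and \code{post}, each a \linkS4class{MeasurementPopulation}.
#' @export
populationsFromTable <- function(table, structure) {
  ids <- unique(table$experiment_id)
  out <- lapply(ids, function(e) {
    sub <- table[table$experiment_id == e, ]
    list(pre = MeasurementPopulation(sub$length_nm[sub$stage == "pre"],
                                     "pre", structure, e),
         post = MeasurementPopulation(sub$length_nm[sub$stage == "post"],
                                      "post", structure, e))
  })
  names(out) <- ids
  out
}
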