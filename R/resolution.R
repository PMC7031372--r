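# Lateral-resolution estimation: 2D symmetric Gaussian + constant
# background, least-squares fitted to a window around each isolated
# sub-diffraction emitter; FWHM = 2 sqrt(2 ln 2) sigma; the population mean
# over emitters is the resolution figure.

#' Fit a 2D Gaussian to one emitter and return its FWHM
#'
#' Levenberg-Marquardt least squares of
#' \code{b + A exp(-((x - x0)^2 + (y - y0)^2) / (2 sigma^2))} over a square
#' window centred on the candidate position. Initialized at the
#' intensity-weighted centroid with sigma from second moments; sigma is
#' bounded to [0.2, 5] times its initial value and a fit that does not
#' converge or ends on a bound is flagged as failed.
#'
#' @param image a \linkS4class{FluorImage}.
#' @param approxCenterNm c(x, y) candidate centre in nm.
#' @param windowNm window side in nm; should be at least 3 expected FWHM.
#' @return list with \code{ok}, \code{centerNm} (c(x, y)), \code{fwhmNm}.
#' @examples
#' bf <- renderBeadField(1, ImagingSpec(psfFwhmNm = 360.51, pixelSizeNm = 100,
#'                                      shotNoise = FALSE, readNoiseSd = 0))
#' fitEmitterFwhm(bf$image, bf$centers[1, ], windowNm = 1500)$fwhmNm
#' @export
fitEmitterFwhm <- function(image, approxCenterNm, windowNm) {
  stopifnot(is(image, "FluorImage"))
  px <- pixelSizeNm(image)
  m <- pixels(image)
  jx <- which(abs((seq_len(ncol(m)) - 0.5) * px - approxCenterNm[1]) <=
                windowNm / 2)
  iy <- which(abs((seq_len(nrow(m)) - 0.5) * px - approxCenterNm[2]) <=
                windowNm / 2)
  if (length(jx) < 4L || length(iy) < 4L)
    stop("window contains too few pixels for a Gaussian fit")
  sub <- m[iy, jx, drop = FALSE]
  xs <- (jx - 0.5) * px
  ys <- (iy - 0.5) * px
  X <- matrix(rep(xs, each = length(ys)), length(ys))
  Y <- matrix(rep(ys, length(xs)), length(ys))

  b0 <- min(sub)
  w <- pmax(sub - b0, 0)
  if (sum(w) == 0) return(list(ok = FALSE, centerNm = approxCenterNm,
                               fwhmNm = NA_real_))
  x0 <- sum(w * X) / sum(w)
  y0 <- sum(w * Y) / sum(w)
  s0 <- sqrt((sum(w * (X - x0)^2) + sum(w * (Y - y0)^2)) / (2 * sum(w)))
  s0 <- max(s0, px / 2)
  df <- data.frame(v = as.vector(sub), x = as.vector(X), y = as.vector(Y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + A * exp(-((x - x0p)^2 + (y - y0p)^2) / (2 * sig^2)),
      data = df,
      start = list(b = b0, A = max(sub) - b0, x0p = x0, y0p = y0, sig = s0),
      lower = c(-Inf, 0, min(xs), min(ys), 0.2 * s0),
      upper = c(Inf, Inf, max(xs), max(ys), 5 * s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(ok = FALSE, centerNm = approxCenterNm, fwhmNm = NA_real_))
  cf <- stats::coef(fit)
  onBound <- cf[["sig"]] <= 0.2 * s0 * 1.0001 || cf[["sig"]] >= 5 * s0 * 0.9999
  list(ok = !onBound, centerNm = c(cf[["x0p"]], cf[["y0p"]]),
       fwhmNm = sigmaToFwhm(cf[["sig"]]))
}

#' Pool emitter fits into a resolution estimate
#'
#' @param fits list of results from \code{\link{fitEmitterFwhm}}.
#' @return A \linkS4class{ResolutionEstimate}: mean and sample SD of the
#'   successful fits; failed fits are excluded and counted. A single
#'   successful fit yields SD 0 with a warning; none is an error.
#' @examples
#' fits <- list(list(ok = TRUE, centerNm = c(0, 0), fwhmNm = 360),
#'              list(ok = TRUE, centerNm = c(0, 0), fwhmNm = 361))
#' populationResolution(fits)
#' @export
populationResolution <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$ok), logical(1))
  if (!any(ok)) stop("no successful emitter fits")
  vals <- vapply(fits[ok], function(f) f$fwhmNm, numeric(1))
  ctrs <- do.call(rbind, lapply(fits[ok], function(f) f$centerNm))
  sdv <- if (length(vals) > 1L) stats::sd(vals) else {
    warning("single emitter: population SD undefined, reported as 0")
    0
  }
  new("ResolutionEstimate", fwhmNm = mean(vals), sdNm = sdv,
      n = as.integer(length(vals)),
      perEmitter = data.frame(x_nm = ctrs[, 1], y_nm = ctrs[, 2],
                              fwhm_nm = vals),
      nFailed = as.integer(sum(!ok)))
}

# Candidate emitters: local 3x3 maxima above background + 5 sigma, where
# background and sigma are the image median and MAD.
detectEmitters <- function(image, minSeparationNm) {
  m <- pixels(image)
  px <- pixelSizeNm(image)
  thr <- stats::median(m) + 5 * stats::mad(m)
  nr <- nrow(m); nc <- ncol(m)
  cand <- NULL
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- m[i, j]
    if (v > thr && v == max(m[(i - 1):(i + 1), (j - 1):(j + 1)]))
      cand <- rbind(cand, c((j - 0.5) * px, (i - 0.5) * px, v))
  }
  if (is.null(cand)) return(matrix(numeric(0), 0, 2))
  cand <- cand[order(-cand[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (a in seq_len(nrow(cand))) {
    if (!keep[a]) next
    if (a < nrow(cand)) {
      d <- sqrt((cand[-(1:a), 1] - cand[a, 1])^2 +
                  (cand[-(1:a), 2] - cand[a, 2])^2)
      keep[-(1:a)][d < minSeparationNm] <- FALSE
    }
  }
  cand[keep, 1:2, drop = FALSE]
}

#' Estimate lateral resolution from a bead-field image
#'
#' Fits every candidate emitter (given, or detected as isolated local maxima
#' above background + 5 sigma) and pools the FWHMs.
#'
#' @param image a \linkS4class{FluorImage} of well-separated beads.
#' @param centers optional n x 2 matrix of candidate centres (nm); detected
#'   automatically when NULL.
#' @param windowNm fit window side (nm); default 4x the expected FWHM.
#' @param expectedFwhmNm expected FWHM used for the default window and the
#'   detection separation rule.
#' @return A \linkS4class{ResolutionEstimate}.
#' @examples
#' bf <- renderBeadField(4, ImagingSpec(psfFwhmNm = 360.51, pixelSizeNm = 100,
#'                                      seed = 7))
#' estimateResolution(bf$image, bf$centers)
#' @export
estimateResolution <- function(image, centers = NULL,
                               windowNm = 4 * expectedFwhmNm,
                               expectedFwhmNm = 400) {
  if (is.null(centers))
    centers <- detectEmitters(image, minSeparationNm = 2 * expectedFwhmNm)
  if (nrow(centers) == 0L) stop("no candidate emitters found")
  fits <- lapply(seq_len(nrow(centers)), function(b)
    fitEmitterFwhm(image, centers[b, ], windowNm))
  populationResolution(fits)
}
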