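# MPS period estimation: profile extraction along a traced line, the
# five-peak rule (first to fifth consecutive bright spot, divided by four)
# with sub-pixel parabolic refinement, rescaling to pre-expansion
# dimensions, and spatial-consistency reporting.

#' Extract an intensity profile along a polyline
#'
#' Samples the image by bilinear interpolation at pixel-size steps along the
#' arc length of the polyline, averaging over a band of the given width
#' perpendicular to the local tangent — the digital equivalent of tracing a
#' line over an axon with a finite line width.
#'
#' @param image a \linkS4class{FluorImage}.
#' @param line two-column matrix of (x, y) nm waypoints, inside the image.
#' @param averagingWidthNm transverse averaging width in nm; must be at
#'   least one pixel.
#' @return A \linkS4class{Profile1D}.
#' @examples
#' img <- FluorImage(matrix(rep(1:10, each = 5), 5, 10), pixelSizeNm = 100)
#' pr <- extractProfile(img, cbind(c(100, 900), c(250, 250)), 100)
#' @export
extractProfile <- function(image, line, averagingWidthNm = pixelSizeNm(image)) {
  stopifnot(is(image, "FluorImage"))
  step <- pixelSizeNm(image)
  if (averagingWidthNm < step)
    stop("averagingWidthNm must be at least one pixel size")
  total <- polyArcLength(line)[nrow(line)]
  s <- seq(0, total, by = step)
  at <- polyPointAt(line, s)
  nrml <- cbind(-at$tangent[, 2], at$tangent[, 1])
  nOff <- max(1L, round(averagingWidthNm / step) + 1L)
  offs <- if (nOff == 1L) 0 else
    seq(-averagingWidthNm / 2, averagingWidthNm / 2, length.out = nOff)
  vals <- vapply(offs, function(o)
    bilinearSample(image, at$point[, 1] + o * nrml[, 1],
                   at$point[, 2] + o * nrml[, 2]),
    numeric(length(s)))
  vals <- matrix(vals, nrow = length(s))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop(sprintf("polyline exits the image near (%.0f, %.0f) nm",
                 at$point[bad, 1], at$point[bad, 2]))
  }
  Profile1D(s, rowMeans(vals), source = "extractProfile")
}

# Local maxima with topographic prominence. Returns data.frame(idx, height,
# prominence), sorted by position.
peakCandidates <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  idx <- idx[y[idx] > y[idx - 1L] & y[idx] >= y[idx + 1L]]
  if (!length(idx))
    return(data.frame(idx = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- if (i > 1) {
      higher <- which(y[seq_len(i - 1L)] > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(y[lo:(i - 1L)])
    } else h
    right <- if (i < n) {
      higher <- which(y[(i + 1L):n] > h)
      hi <- if (length(higher)) i + min(higher) - 1L else n
      min(y[(i + 1L):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
  data.frame(idx = idx, height = y[idx], prominence = prom)
}

#' Estimate the MPS period by the five-peak rule
#'
#' Detects local intensity maxima whose topographic prominence exceeds a
#' fraction of the profile's robust amplitude (95th minus 5th percentile) and
#' that are separated by at least half the expected period, refines each peak
#' position by three-point parabolic interpolation, selects five consecutive
#' peaks (when more exist, the window whose four spacings have minimal
#' variance, ties broken leftmost), and returns the distance from the first
#' to the fifth peak divided by four.
#'
#' @param profile a \linkS4class{Profile1D}, in acquisition-space nm.
#' @param expectedPeriodNm expected spacing in the same space as the profile
#'   (for an expanded sample, the pre-expansion period times the expansion
#'   factor); only used for the minimum-separation rule.
#' @param prominenceFrac prominence threshold as a fraction of the robust
#'   amplitude (default 0.2).
#' @return A \linkS4class{PeriodEstimate} with \code{factorApplied = 1}.
#' @examples
#' pr <- Profile1D(seq(0, 1100, by = 50),
#'                 1 + cos(2 * pi * seq(0, 1100, by = 50) / 190))
#' periodNm(fivePeakPeriod(pr, expectedPeriodNm = 190))
#' @export
fivePeakPeriod <- function(profile, expectedPeriodNm = 190,
                           prominenceFrac = 0.2) {
  stopifnot(is(profile, "Profile1D"))
  pos <- profile@positionsNm
  y <- profile@intensities
  amp <- diff(stats::quantile(y, c(0.05, 0.95), names = FALSE))
  cand <- peakCandidates(y)
  cand <- cand[cand$prominence >= prominenceFrac * amp, , drop = FALSE]
  # enforce minimum separation of half the expected period, keeping the
  # more prominent peak of any conflicting pair
  if (nrow(cand) > 1L) {
    keep <- logical(nrow(cand))
    for (o in order(-cand$prominence)) {
      if (!any(keep & abs(pos[cand$idx] - pos[cand$idx[o]]) <
                 expectedPeriodNm / 2))
        keep[o] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand$idx), , drop = FALSE]
  }
  if (nrow(cand) < 5L)
    stop(sprintf("insufficient peaks: found %d, need 5", nrow(cand)))

  refine <- function(i) {
    if (i <= 1L || i >= length(y)) return(pos[i])
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (denom >= 0) return(pos[i])
    d <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
    d <- max(min(d, 0.5), -0.5)
    step <- (pos[i + 1L] - pos[i - 1L]) / 2
    pos[i] + d * step
  }
  refined <- vapply(cand$idx, refine, numeric(1))
  if (any(diff(refined) <= 0))
    stop("refined peak positions are not strictly increasing")

  nWin <- length(refined) - 4L
  if (nWin > 1L) {
    v <- vapply(seq_len(nWin), function(w)
      stats::var(diff(refined[w:(w + 4L)])), numeric(1))
    w <- which.min(v)   # which.min takes the leftmost tie
  } else w <- 1L
  peaks <- refined[w:(w + 4L)]
  new("PeriodEstimate", periodNm = (peaks[5] - peaks[1]) / 4, nPeriods = 4L,
      factorApplied = 1, peakPositionsNm = peaks)
}

#' Rescale a period estimate to pre-expansion dimensions
#'
#' Divides an acquisition-space period by the expansion factor of its
#' experiment. Applying a factor twice is an error: the estimate records the
#' factor already applied.
#'
#' @param est a \linkS4class{PeriodEstimate} with \code{factorApplied = 1}.
#' @param factor the experiment's expansion factor (>= 1).
#' @return a rescaled \linkS4class{PeriodEstimate}.
#' @examples
#' est <- new("PeriodEstimate", periodNm = 889.2, nPeriods = 4L,
#'            factorApplied = 1, peakPositionsNm = 889.2 * (0:4))
#' periodNm(rescalePeriod(est, 4.68))  # 190
#' @export
rescalePeriod <- function(est, factor) {
  stopifnot(is(est, "PeriodEstimate"))
  if (factor < 1) stop("factor must be >= 1")
  if (est@factorApplied != 1)
    stop("estimate was already rescaled by factor ", est@factorApplied)
  new("PeriodEstimate", periodNm = est@periodNm / factor,
      nPeriods = est@nPeriods, factorApplied = factor,
      peakPositionsNm = est@peakPositionsNm / factor)
}

#' Maximum pairwise relative difference among group mean periods
#'
#' Spatial-consistency check: given period estimates grouped by sub-region
#' (or by distant region of the same gel), computes each group's mean and
#' returns the maximum over group pairs of the absolute difference relative
#' to the pair's mean, in percent. Under homogeneous expansion this should
#' stay within the sampling dispersion of the period.
#'
#' @param groups named list; each element is a numeric vector of periods (nm)
#'   or a list of \linkS4class{PeriodEstimate} objects.
#' @return list with \code{max_diff_pct}, \code{group_means} (named) and
#'   \code{pairwise} (data.frame).
#' @examples
#' consistencyReport(list(a = c(190, 190), b = c(199, 200)))$max_diff_pct
#' @export
consistencyReport <- function(groups) {
  if (length(groups) < 2L) stop("at least two groups are required")
  vals <- lapply(groups, function(g) {
    if (is.list(g)) vapply(g, periodNm, numeric(1)) else as.numeric(g)
  })
  if (any(lengths(vals) == 0L)) stop("empty group in consistency report")
  means <- vapply(vals, mean, numeric(1))
  cmb <- utils::combn(length(means), 2)
  pct <- apply(cmb, 2, function(ij) {
    a <- means[ij[1]]; b <- means[ij[2]]
    100 * abs(a - b) / ((a + b) / 2)
  })
  pairwise <- data.frame(group_a = names(means)[cmb[1, ]],
                         group_b = names(means)[cmb[2, ]],
                         diff_pct = pct, stringsAsFactors = FALSE)
  list(max_diff_pct = max(pct), group_means = means, pairwise = pairwise)
}
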