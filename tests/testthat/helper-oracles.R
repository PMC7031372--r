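# Independent oracles used to cross-check the analysis path. These are
# deliberately separate implementations (brute force / closed form), not
# calls into the code they verify.

# Brute-force five-peak oracle: every interior local maximum (no prominence
# rule), parabolic refinement written out independently, every window of 5
# consecutive maxima; the window whose refined peaks have minimal squared
# residual to a perfect lattice wins. Returns the period of that window.
oracleFivePeak <- function(positions, values) {
  n <- length(values)
  idx <- which(values[2:(n - 1)] > values[1:(n - 2)] &
                 values[2:(n - 1)] >= values[3:n]) + 1L
  stopifnot(length(idx) >= 5L)
  ref <- sapply(idx, function(i) {
    a <- values[i - 1]; b <- values[i]; c <- values[i + 1]
    den <- a - 2 * b + c
    if (den >= 0) return(positions[i])
    positions[i] + max(min(0.5 * (a - c) / den, 0.5), -0.5) *
      (positions[i + 1] - positions[i - 1]) / 2
  })
  best <- Inf; bestPeriod <- NA_real_
  for (w in 1:(length(ref) - 4L)) {
    p <- ref[w:(w + 4L)]
    period <- (p[5] - p[1]) / 4
    resid <- sum((p - (p[1] + 0:4 * period))^2)
    if (resid < best) { best <- resid; bestPeriod <- period }
  }
  bestPeriod
}

# First non-zero-lag local maximum of the autocorrelation of a uniformly
# sampled profile, in nm.
oracleAutocorrPeriod <- function(values, stepNm) {
  x <- values - mean(values)
  n <- length(x)
  ac <- sapply(0:(n - 3), function(k)
    sum(x[1:(n - k)] * x[(1 + k):n]))
  k <- which(ac[2:(length(ac) - 1)] > ac[1:(length(ac) - 2)] &
               ac[2:(length(ac) - 1)] >= ac[3:length(ac)])
  stopifnot(length(k) >= 1L)
  k[1] * stepNm   # ac index 1 is lag 0; first interior max is lag k[1]
}

# Gaussian-equivalent width of a uniform disk (radius R) blurred by a
# Gaussian PSF: variances add, the disk contributing R^2 / 4 per axis.
oracleQuadratureFwhm <- function(psfFwhmNm, beadDiameterNm) {
  sig <- psfFwhmNm / (2 * sqrt(2 * log(2)))
  2 * sqrt(2 * log(2)) * sqrt(sig^2 + (beadDiameterNm / 2)^2 / 4)
}

# Exhaustive phase search of the template correlation, built from its own
# stripe formula: cor(segment, stripes(phase)) over every integer-pixel
# phase in one period; returns the maximum and the argmax shift (nm).
oraclePhaseSearch <- function(segMatrix, periodNm, stripeSigmaNm, pxNm) {
  x <- (seq_len(ncol(segMatrix)) - 0.5) * pxNm
  shifts <- (seq_len(max(1, round(periodNm / pxNm))) - 1L) * pxNm
  rs <- sapply(shifts, function(s) {
    prof <- rowSums(sapply(-8:60, function(k)
      exp(-(x - s - k * periodNm)^2 / (2 * stripeSigmaNm^2))))
    tpl <- matrix(prof - mean(prof), nrow(segMatrix), ncol(segMatrix),
                  byrow = TRUE)
    stats::cor(as.vector(segMatrix), as.vector(tpl))
  })
  list(r = max(rs), shiftNm = shifts[which.max(rs)])
}

# A synthetic 1D lattice profile: Gaussian peaks at phase + k * period plus
# optional i.i.d. Gaussian noise under a fixed seed.
latticeProfile <- function(periodNm, nPeaks = 7, stepNm = 20, sigmaNm = 40,
                           phaseNm = periodNm / 2, noiseSd = 0, seed = 1) {
  total <- phaseNm * 2 + (nPeaks - 1) * periodNm
  pos <- seq(0, total, by = stepNm)
  y <- rowSums(sapply(seq_len(nPeaks) - 1,
                      function(k) exp(-(pos - phaseNm - k * periodNm)^2 /
                                        (2 * sigmaNm^2))))
  if (noiseSd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noiseSd)
  }
  list(positions = pos, values = y)
}

quietImaging <- function(fwhm, px, seed = 1L)
  ImagingSpec(psfFwhmNm = fwhm, pixelSizeNm = px, readNoiseSd = 0,
              shotNoise = FALSE, seed = seed)
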