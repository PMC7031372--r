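# Internal geometry / numeric helpers shared across modules.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

fwhmToSigma <- function(fwhm) fwhm * FWHM_TO_SIGMA
sigmaToFwhm <- function(sigma) sigma / FWHM_TO_SIGMA

# Run expr under a fixed seed without disturbing the caller's RNG stream.
localSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item child seed from a parent seed; stays below 2^31.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

# Cumulative arc length of a two-column polyline (nm).
polyArcLength <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

# Point and unit tangent at arc-length positions s along a polyline.
# Returns list(point = n x 2, tangent = n x 2). s clamped to [0, total].
polyPointAt <- function(pts, s) {
  cs <- polyArcLength(pts)
  total <- cs[length(cs)]
  s <- pmin(pmax(s, 0), total)
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(pts) - 1L)
  seg <- pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  tangent <- seg / len
  frac <- (s - cs[idx]) / len
  point <- pts[idx, , drop = FALSE] + tangent * frac * len
  list(point = point, tangent = tangent)
}

# Bilinear interpolation of a FluorImage at physical (x, y) nm coordinates.
# Points must lie within the physical extent of the raster; out-of-range
# points yield NA.
bilinearSample <- function(image, x, y) {
  px <- image@pixelSizeNm
  m <- image@pixels
  nr <- nrow(m); nc <- ncol(m)
  fx <- x / px + 0.5   # fractional column index (pixel centres at integers)
  fy <- y / px + 0.5
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= nc * px & y >= 0 & y <= nr * px
  if (!any(ok)) return(out)
  # clamp to the centre lattice so edge points use the edge pixel value
  fxc <- pmin(pmax(fx[ok], 1), nc)
  fyc <- pmin(pmax(fy[ok], 1), nr)
  j0 <- pmin(floor(fxc), nc - 1L); i0 <- pmin(floor(fyc), nr - 1L)
  dx <- fxc - j0; dy <- fyc - i0
  v <- m[cbind(i0, j0)] * (1 - dx) * (1 - dy) +
       m[cbind(i0, j0 + 1L)] * dx * (1 - dy) +
       m[cbind(i0 + 1L, j0)] * (1 - dx) * dy +
       m[cbind(i0 + 1L, j0 + 1L)] * dx * dy
  out[ok] <- v
  out
}

# FNV-1a hash of a serialized R object, as 8 hex digits; used to stamp
# outputs with their generating configuration.
configHash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
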