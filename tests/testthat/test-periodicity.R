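test_that("five-peak rule on an exact lattice returns the planted spacing", {
  lp <- latticeProfile(190, nPeaks = 5, stepNm = 10, sigmaNm = 35)
  est <- fivePeakPeriod(Profile1D(lp$positions, lp$values), 190)
  expect_equal(periodNm(est), 190, tolerance = 1e-6)
  expect_length(peakPositionsNm(est), 5)
  # expanded-space lattice: 190 nm x 4.68
  lpE <- latticeProfile(889.2, nPeaks = 5, stepNm = 100, sigmaNm = 170)
  estE <- fivePeakPeriod(Profile1D(lpE$positions, lpE$values), 889.2)
  expect_equal(periodNm(estE), 889.2, tolerance = 0.01)
})

test_that("five-peak estimate is invariant to affine intensity maps and translation", {
  lp <- latticeProfile(190, nPeaks = 6, stepNm = 20, sigmaNm = 40,
                       noiseSd = 0.04, seed = 12)
  base <- periodNm(fivePeakPeriod(Profile1D(lp$positions, lp$values), 190))
  aff <- periodNm(fivePeakPeriod(
    Profile1D(lp$positions, 3.2 * lp$values + 17), 190))
  shf <- periodNm(fivePeakPeriod(
    Profile1D(lp$positions + 5000, lp$values), 190))
  expect_equal(aff, base, tolerance = 1e-12)
  expect_equal(shf, base, tolerance = 1e-9)
})

test_that("noisy profiles match the exhaustive five-peak oracle within 1 nm", {
  for (seed in 1:5) {
    lp <- latticeProfile(190, nPeaks = 7, stepNm = 20, sigmaNm = 40,
                         noiseSd = 0.05, seed = seed)
    est <- fivePeakPeriod(Profile1D(lp$positions, lp$values), 190)
    expect_equal(periodNm(est), oracleFivePeak(lp$positions, lp$values),
                 tolerance = 1)
  }
})

test_that("too few peaks is a clean error", {
  lp <- latticeProfile(190, nPeaks = 4, stepNm = 10, sigmaNm = 35)
  expect_error(fivePeakPeriod(Profile1D(lp$positions, lp$values), 190),
               "insufficient peaks")
})

test_that("rescaling divides by the factor once and only once", {
  lpE <- latticeProfile(889.2, nPeaks = 5, stepNm = 100, sigmaNm = 170)
  est <- fivePeakPeriod(Profile1D(lpE$positions, lpE$values), 889.2)
  resc <- rescalePeriod(est, 4.68)
  expect_equal(periodNm(resc), periodNm(est) / 4.68)
  expect_equal(factorApplied(resc), 4.68)
  expect_error(rescalePeriod(resc, 4.68), "already rescaled")
  # gel-factor rescaling of the same raw value overestimates the period
  expect_equal(periodNm(rescalePeriod(est, 3.55)),
               periodNm(est) / 3.55, tolerance = 1e-12)
  same <- rescalePeriod(est, 1)
  expect_equal(periodNm(same), periodNm(est))
})

test_that("a 45-degree line recovers the same period as an axis-aligned one", {
  im <- quietImaging(90, 20)
  f <- ExpansionSpec(1)
  gtH <- straightAxon(190 * 8, im, f, periodNm = 190)
  renH <- renderAxon(gtH, im, f)
  pH <- periodNm(fivePeakPeriod(
    extractProfile(renH$image, renH$groundTruth@centerline, 40), 190))
  off <- gtH@centerline[1, 1]
  len <- 190 * 8 / sqrt(2)
  gtD <- AxonGroundTruth(cbind(c(off, off + len), c(off, off + len)),
                         periodNm = 190)
  renD <- renderAxon(gtD, im, f)
  pD <- periodNm(fivePeakPeriod(
    extractProfile(renD$image, renD$groundTruth@centerline, 40), 190))
  expect_equal(pD, pH, tolerance = 0.02 * pH)
})

test_that("profile extraction reports the coordinate where a polyline leaves the image", {
  img <- FluorImage(matrix(1, 10, 10), 100)
  expect_error(extractProfile(img, cbind(c(500, 2500), c(500, 500)), 100),
               "exits the image")
  expect_error(extractProfile(img, cbind(c(100, 900), c(500, 500)), 10),
               "at least one pixel")
})

test_that("consistency report computes max pairwise relative difference of means", {
  expect_equal(consistencyReport(list(a = c(190, 190),
                                      b = c(190)))$max_diff_pct, 0)
  r <- consistencyReport(list(a = 190, b = 199.5))
  expect_equal(r$max_diff_pct, 100 * 9.5 / 194.75, tolerance = 1e-9)
  expect_error(consistencyReport(list(a = 190)), "two groups")
  expect_error(consistencyReport(list(a = 190, b = numeric(0))),
               "empty group")
})

test_that("simulated homogeneous ROIs agree to better than 5 percent", {
  groups <- lapply(1:4, function(g) {
    ests <- lapply(1:8, function(i) {
      im <- ImagingSpec(360.51, 100, seed = 7000L + 10L * g + i)
      rescalePeriod(simulatePeriodMeasurement(im, ExpansionSpec(4.68), 190),
                    4.68)
    })
    vapply(ests, periodNm, numeric(1))
  })
  names(groups) <- paste0("roi", 1:4)
  expect_lt(consistencyReport(groups)$max_diff_pct, 5)
})

test_that("period error does not improve as the PSF degrades", {
  errAt <- function(fwhm) {
    ests <- sapply(1:6, function(i) {
      im <- ImagingSpec(fwhm, 20, seed = 900L + i)
      periodNm(simulatePeriodMeasurement(im, ExpansionSpec(1), 190))
    })
    mean(abs(ests - 190))
  }
  errs <- sapply(c(60, 100, 140), errAt)
  expect_true(all(diff(errs) > -0.5))  # non-decreasing up to noise jitter
})
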