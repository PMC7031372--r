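test_that("noiseless axial profile is periodic at period x factor (autocorrelation)", {
  for (f in c(1, 2, 4.68)) {
    px <- if (f > 2) 100 else 20
    im <- quietImaging(if (f > 2) 360.51 else 90, px)
    gt <- straightAxon(190 * 8, im, ExpansionSpec(f), periodNm = 190)
    ren <- renderAxon(gt, im, ExpansionSpec(f))
    prof <- extractProfile(ren$image, ren$groundTruth@centerline, 2 * px)
    lag <- oracleAutocorrPeriod(prof@intensities,
                                diff(prof@positionsNm[1:2]))
    expect_lt(abs(lag - 190 * f), px + 1e-9)
  }
})

test_that("expansion scales every planted ring coordinate exactly", {
  im <- ImagingSpec(360.51, 100, seed = 21L)
  # offset generous enough for the render margin at both factors
  gt <- AxonGroundTruth(cbind(c(2500, 2500 + 190 * 8), c(2500, 2500)),
                        periodNm = 190, ringDropoutP = 0.3,
                        phaseJitterSdNm = 25)
  r1 <- renderAxon(gt, im, ExpansionSpec(1))
  r468 <- renderAxon(gt, im, ExpansionSpec(4.68))
  expect_equal(nrow(r1$groundTruth@ringCentersNm),
               nrow(r468$groundTruth@ringCentersNm))
  expect_equal(r468$groundTruth@ringCentersNm,
               r1$groundTruth@ringCentersNm * 4.68, tolerance = 1e-12)
  expect_equal(r468$groundTruth@ringArcNm,
               r1$groundTruth@ringArcNm * 4.68, tolerance = 1e-12)
})

test_that("renders are bit-reproducible under identical seeds", {
  im <- ImagingSpec(360.51, 100, seed = 77L)
  gt <- straightAxon(190 * 6, im, ExpansionSpec(4.68), periodNm = 190)
  a <- renderAxon(gt, im, ExpansionSpec(4.68))
  b <- renderAxon(gt, im, ExpansionSpec(4.68))
  expect_identical(pixels(a$image), pixels(b$image))
  bf1 <- renderBeadField(5, ImagingSpec(360.51, 100, seed = 3L))
  bf2 <- renderBeadField(5, ImagingSpec(360.51, 100, seed = 3L))
  expect_identical(pixels(bf1$image), pixels(bf2$image))
  expect_identical(bf1$centers, bf2$centers)
})

test_that("mean intensity above background is linear in ring amplitude", {
  im <- quietImaging(360.51, 100)
  mk <- function(a) {
    gt <- straightAxon(190 * 6, im, ExpansionSpec(4.68), periodNm = 190,
                       amplitude = a, background = 7)
    mean(pixels(renderAxon(gt, im, ExpansionSpec(4.68))$image)) - 7
  }
  expect_equal(mk(160) / mk(80), 2, tolerance = 1e-9)
})

test_that("degraded render with zero dropout and jitter equals the pristine render", {
  im <- ImagingSpec(360.51, 100, seed = 5L)
  gt <- straightAxon(190 * 6, im, ExpansionSpec(4.68), periodNm = 190)
  expect_identical(pixels(renderAxon(gt, im, ExpansionSpec(4.68))$image),
                   pixels(renderDegradedAxon(gt, im,
                                             ExpansionSpec(4.68))$image))
})

test_that("renderer rejects geometry that does not fit", {
  im <- quietImaging(360.51, 100)
  gtNear <- AxonGroundTruth(cbind(c(10, 2000), c(10, 10)), periodNm = 190)
  expect_error(renderAxon(gtNear, im, ExpansionSpec(1)), "margin")
  gt <- straightAxon(190 * 6, im, ExpansionSpec(1), periodNm = 190)
  expect_error(renderAxon(gt, im, ExpansionSpec(1), fovNm = c(1000, 1000)),
               "field of view")
  expect_error(renderBeadField(0, im), "at least one bead")
  expect_error(renderBeadField(9, im, fovNm = c(2000, 2000)), "too small")
})

test_that("population sampling: degenerate zero-variation case gives exact ratios", {
  tab <- samplePopulation(PopulationSpec(3, 5, 20000, cv = 0,
                                         measurementCv = 0, seed = 2L),
                          ExpansionSpec(4))
  for (e in unique(tab$experiment_id)) {
    sub <- tab[tab$experiment_id == e, ]
    ratio <- mean(sub$length_nm[sub$stage == "post"]) /
      mean(sub$length_nm[sub$stage == "pre"])
    expect_equal(ratio, 4, tolerance = 1e-12)
  }
})

test_that("population sampling at factor 1 calibrates to 1 within sampling error", {
  tab <- samplePopulation(PopulationSpec(6, 40, 25000, cv = 0.15,
                                         measurementCv = 0.02, seed = 4L),
                          ExpansionSpec(1))
  expect_equal(exFactor(calibrateTable(tab, "protein-structure")), 1,
               tolerance = 0.02)
})

test_that("bead field places beads at least five FWHM apart", {
  bf <- renderBeadField(12, ImagingSpec(360.51, 100, seed = 8L))
  d <- as.matrix(dist(bf$centers))
  diag(d) <- Inf
  expect_gte(min(d), 5 * 360.51)
})
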