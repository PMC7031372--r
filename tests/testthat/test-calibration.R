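mkPop <- function(lengths, stage, structure = "gel", id = "e1")
  MeasurementPopulation(lengths, stage, structure, id)

test_that("expansion factor is the ratio of population means", {
  expect_equal(exFactor(expansionFactor(mkPop(c(10, 12, 11), "pre"),
                                        mkPop(c(40, 48, 44), "post"))), 4)
  expect_equal(exFactor(expansionFactor(mkPop(c(7, 9), "pre"),
                                        mkPop(c(7, 9), "post"))), 1)
})

test_that("calibration rejects malformed inputs", {
  expect_error(expansionFactor(mkPop(1:3, "post"), mkPop(4:6, "post")),
               "order")
  expect_error(expansionFactor(mkPop(1:3, "pre", "gel"),
                               mkPop(4:6, "post", "protein-structure")),
               "structures")
  expect_error(MeasurementPopulation(numeric(0), "pre", "gel"), "non-empty")
  expect_error(MeasurementPopulation(c(1, -2), "pre", "gel"), "> 0")
})

test_that("pooling averages per-experiment factors and reports their SD", {
  res <- lapply(seq_along(c(3.5, 3.6, 3.6)), function(i)
    expansionFactor(mkPop(10, "pre", id = paste0("e", i)),
                    mkPop(10 * c(3.5, 3.6, 3.6)[i], "post",
                          id = paste0("e", i))))
  pooled <- poolExperiments(res)
  expect_equal(exFactor(pooled), mean(c(3.5, 3.6, 3.6)), tolerance = 1e-9)
  expect_equal(pooled@sd, sd(c(3.5, 3.6, 3.6)), tolerance = 1e-9)
  expect_warning(single <- poolExperiments(res[1]), "single experiment")
  expect_equal(exFactor(single), 3.5)
  expect_equal(single@sd, 0)
  mixed <- expansionFactor(mkPop(10, "pre", "protein-structure"),
                           mkPop(40, "post", "protein-structure"))
  expect_error(poolExperiments(list(res[[1]], mixed)), "mixed structures")
})

test_that("calibration is scale equivariant and inverts", {
  pre <- c(9, 11, 10.5); post <- c(36, 40, 44)
  f0 <- exFactor(expansionFactor(mkPop(pre, "pre"), mkPop(post, "post")))
  f2 <- exFactor(expansionFactor(mkPop(pre, "pre"), mkPop(post * 2, "post")))
  expect_equal(f2, 2 * f0, tolerance = 1e-12)
  fsame <- exFactor(expansionFactor(mkPop(pre * 3, "pre"),
                                    mkPop(post * 3, "post")))
  expect_equal(fsame, f0, tolerance = 1e-12)
  finv <- exFactor(expansionFactor(mkPop(post, "pre"), mkPop(pre, "post")))
  expect_equal(f0 * finv, 1, tolerance = 1e-12)
})

test_that("expected resolution divides FWHM by the factor and decreases in it", {
  expect_equal(expectedResolution(360.51, 1), 360.51)
  expect_equal(expectedResolution(200, 4), 50)
  factors <- seq(1, 6, by = 0.5)
  vals <- sapply(factors, function(f) expectedResolution(360.51, f))
  expect_true(all(diff(vals) < 0))
  expect_error(expectedResolution(-1, 2), "> 0")
  expect_error(expectedResolution(100, 0.5), ">= 1")
})

test_that("factor discrepancy reports pooled and paired statistics", {
  mkres <- function(facs, structure) poolExperiments(lapply(
    seq_along(facs), function(i)
      expansionFactor(mkPop(10, "pre", structure, paste0("e", i)),
                      mkPop(10 * facs[i], "post", structure, paste0("e", i)))))
  gel <- mkres(c(3.5, 3.6), "gel")
  prot <- mkres(c(4.62, 4.74), "protein-structure")
  d <- factorDiscrepancy(gel, prot)
  # hand arithmetic: mean of (4.62/3.5 - 1, 4.74/3.6 - 1) in percent
  expect_equal(d$paired_mean_pct, mean(c(32, 31 + 2 / 3)), tolerance = 1e-9)
  expect_equal(d$pooled_pct, 100 * (4.68 - 3.55) / 3.55, tolerance = 1e-9)
  eq <- factorDiscrepancy(mkres(c(3.55, 3.55), "gel"),
                          mkres(c(3.55, 3.55), "protein-structure"))
  expect_equal(eq$pooled_pct, 0)
  expect_error(factorDiscrepancy(prot, gel), "gel")
})

test_that("pooled estimator recovers planted factors on synthetic populations", {
  for (f in c(1, 3.55, 4.68)) {
    tab <- samplePopulation(PopulationSpec(6, 40, 25000, cv = 0.15,
                                           measurementCv = 0.02,
                                           seed = round(100 * f)),
                            ExpansionSpec(f))
    est <- exFactor(calibrateTable(tab, "protein-structure"))
    expect_equal(est, f, tolerance = 0.02 * f)
  }
})
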