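# End-to-end study runners: simulate -> calibrate -> measure -> score ->
# report, with every source of randomness funnelled through named seeds
# derived from one config seed, and outputs stamped with a config hash.

#' Default run configuration
#'
#' All simulation and analysis parameters of the three study runners, as a
#' nested list that round-trips through YAML unchanged. Defaults encode the
#' study conditions: 6 experiments of 3 gel diameters (5 mm scale, CV 3%)
#' and 40 nucleus diameters (25 um scale, CV 15%) for calibration with
#' planted factors 3.55 (gel) and 4.68 (protein structure); widefield
#' imaging at 360.51 nm FWHM sampled at 100 nm/px and a STED-like reference
#' at 90 nm FWHM sampled at 20 nm/px; a 190 nm planted lattice period; 30
#' five-peak measurements per condition; 1 um x 1 um correlation scoring at
#' threshold 0.12.
#'
#' @param seed master integer seed.
#' @return nested configuration list.
#' @examples
#' cfg <- defaultRunConfig(seed = 1)
#' names(cfg)
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    calibration = list(
      gel = list(nExperiments = 6L, nItemsPerExperiment = 3L,
                 meanLengthNm = 5e6, cv = 0.03, measurementCv = 0.01,
                 factor = 3.55),
      protein = list(nExperiments = 6L, nItemsPerExperiment = 40L,
                     meanLengthNm = 25000, cv = 0.15, measurementCv = 0.02,
                     factor = 4.68)),
    imaging = list(
      widefield = list(psfFwhmNm = 360.51, pixelSizeNm = 100,
                       readNoiseSd = 3, shotNoise = TRUE),
      sted = list(psfFwhmNm = 90, pixelSizeNm = 20,
                  readNoiseSd = 3, shotNoise = TRUE)),
    axon = list(periodNm = 190, ringSigmaNm = 15, axonWidthNm = 400,
                amplitude = 80, background = 10),
    expansion = list(factorProtein = 4.68, factorGel = 3.55),
    period = list(nSegments = 30L, lattices = 8L),
    scoring = list(sizeNm = 1000, threshold = 0.12, nAxonsPerGroup = 10L,
                   axonLengthNm = 3200,
                   degraded = list(ringDropoutP = 0.5, phaseJitterSdNm = 60))
  )
}

#' Read / write a run configuration (YAML)
#' @param path YAML file path.
#' @return \code{readRunConfig}: the configuration list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @param config configuration list.
#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

imagingFromConfig <- function(ic, seed) {
  ImagingSpec(psfFwhmNm = ic$psfFwhmNm, pixelSizeNm = ic$pixelSizeNm,
              readNoiseSd = ic$readNoiseSd, shotNoise = ic$shotNoise,
              seed = seed)
}

#' Place a straight axon safely inside an auto-sized field of view
#'
#' Convenience constructor: a horizontal centerline of the given
#' pre-expansion length, offset from the origin by the render margin the
#' imaging and expansion settings will require.
#'
#' @param lengthNm pre-expansion centerline length (nm).
#' @param imaging an \linkS4class{ImagingSpec}.
#' @param expansion an \linkS4class{ExpansionSpec}.
#' @param extraMarginNm additional acquisition-space margin (nm) beyond the
#'   render margin, e.g. to keep square scoring tiles inside the image.
#' @param ... further arguments to \code{\link{AxonGroundTruth}}.
#' @return An \linkS4class{AxonGroundTruth}.
#' @export
straightAxon <- function(lengthNm, imaging, expansion = ExpansionSpec(1),
                         extraMarginNm = 0, ...) {
  gt0 <- AxonGroundTruth(cbind(c(0, lengthNm), c(0, 0)), ...)
  f <- expansion@factor
  margin <- 3 * imaging@psfFwhmNm + gt0@axonWidthNm * f / 2 + extraMarginNm
  off <- (margin + 2 * imaging@pixelSizeNm) / f
  gt0@centerline <- cbind(c(off, off + lengthNm), c(off, off))
  gt0
}

#' Measure one simulated MPS period by the five-peak rule
#'
#' Renders one straight axon segment, extracts the axial intensity profile
#' along the (expanded) centerline with transverse averaging over 80% of the
#' axon width, and applies the five-peak rule. The returned estimate is in
#' acquisition-space nm (\code{factorApplied = 1}).
#'
#' @param imaging an \linkS4class{ImagingSpec} (its seed drives the render).
#' @param expansion an \linkS4class{ExpansionSpec}.
#' @param periodNm planted pre-expansion period.
#' @param lattices number of lattice periods on the segment (default 8,
#'   comfortably above the five peaks the rule needs).
#' @param ... further \code{\link{AxonGroundTruth}} parameters.
#' @return A \linkS4class{PeriodEstimate}.
#' @export
simulatePeriodMeasurement <- function(imaging, expansion = ExpansionSpec(1),
                                      periodNm = 190, lattices = 8L, ...) {
  gt <- straightAxon(lengthNm = periodNm * lattices, imaging, expansion,
                     periodNm = periodNm, ...)
  ren <- renderAxon(gt, imaging, expansion)
  f <- expansion@factor
  width <- 0.8 * gt@axonWidthNm * f
  prof <- extractProfile(ren$image, ren$groundTruth@centerline, width)
  fivePeakPeriod(prof, expectedPeriodNm = periodNm * f)
}

# n five-peak measurements under one condition; returns raw (acquisition
# space) estimates.
measurePeriods <- function(n, imagingCfg, expansion, axonCfg, baseSeed,
                           lattices = 8L) {
  lapply(seq_len(n), function(i) {
    im <- imagingFromConfig(imagingCfg, childSeed(baseSeed, i))
    simulatePeriodMeasurement(im, expansion, periodNm = axonCfg$periodNm,
                              lattices = lattices,
                              ringSigmaNm = axonCfg$ringSigmaNm,
                              axonWidthNm = axonCfg$axonWidthNm,
                              amplitude = axonCfg$amplitude,
                              background = axonCfg$background)
  })
}

#' Run the expansion-factor calibration study
#'
#' Simulates gel-diameter and nucleus-diameter populations with distinct
#' planted factors, estimates both expansion factors by the
#' ratio-of-population-means estimator pooled over experiments, and reports
#' their discrepancy.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @param outDir optional output directory for CSV/JSON reports.
#' @return list with \code{gel} and \code{protein}
#'   (\linkS4class{CalibrationResult}), \code{discrepancy} (list),
#'   \code{tables} (the simulated populations) and \code{configHash}.
#' @examples
#' res <- runCalibrationStudy(defaultRunConfig(seed = 1))
#' exFactor(res$protein)
#' @export
runCalibrationStudy <- function(config = defaultRunConfig(), outDir = NULL) {
  mkPop <- function(cc, k) {
    spec <- PopulationSpec(cc$nExperiments, cc$nItemsPerExperiment,
                           cc$meanLengthNm, cc$cv, cc$measurementCv,
                           seed = childSeed(config$seed, k))
    samplePopulation(spec, ExpansionSpec(cc$factor))
  }
  gelTab <- mkPop(config$calibration$gel, 101L)
  protTab <- mkPop(config$calibration$protein, 202L)
  gel <- calibrateTable(gelTab, "gel")
  prot <- calibrateTable(protTab, "protein-structure")
  disc <- factorDiscrepancy(gel, prot)
  out <- list(gel = gel, protein = prot, discrepancy = disc,
              tables = list(gel = gelTab, protein = protTab),
              configHash = configHash(config))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePopulationCsv(gelTab, file.path(outDir, "population_gel.csv"))
    writePopulationCsv(protTab, file.path(outDir, "population_protein.csv"))
    jsonlite::write_json(list(
      config_hash = out$configHash,
      gel = list(factor = exFactor(gel), sd = gel@sd,
                 per_experiment = perExperiment(gel)),
      protein = list(factor = exFactor(prot), sd = prot@sd,
                     per_experiment = perExperiment(prot)),
      discrepancy = disc),
      file.path(outDir, "calibration.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  out
}

#' Run the period-measurement study
#'
#' Simulates 30 (configurable) five-peak period measurements per condition:
#' a STED-like acquisition of unexpanded axons, and one set of expanded-axon
#' acquisitions rescaled either by the correct protein-structure factor or by
#' the gel-block factor. The same expanded renders feed both rescalings, so
#' the difference between the two conditions isolates the calibration
#' choice.
#'
#' @inheritParams runCalibrationStudy
#' @return list with \code{table} (data.frame condition/period_nm),
#'   \code{summary} (per-condition mean and SD) and \code{configHash}.
#' @export
runPeriodStudy <- function(config = defaultRunConfig(), outDir = NULL) {
  n <- config$period$nSegments
  ax <- config$axon
  fP <- config$expansion$factorProtein
  fG <- config$expansion$factorGel

  sted <- measurePeriods(n, config$imaging$sted, ExpansionSpec(1), ax,
                         childSeed(config$seed, 301L), config$period$lattices)
  exm <- measurePeriods(n, config$imaging$widefield, ExpansionSpec(fP), ax,
                        childSeed(config$seed, 302L), config$period$lattices)
  tab <- rbind(
    data.frame(condition = "sted",
               period_nm = vapply(sted, periodNm, numeric(1))),
    data.frame(condition = "exm_protein_factor",
               period_nm = vapply(exm, function(e)
                 periodNm(rescalePeriod(e, fP)), numeric(1))),
    data.frame(condition = "exm_gel_factor",
               period_nm = vapply(exm, function(e)
                 periodNm(rescalePeriod(e, fG)), numeric(1))))
  summ <- do.call(rbind, lapply(split(tab$period_nm, tab$condition),
                                function(v) data.frame(mean_nm = mean(v),
                                                       sd_nm = stats::sd(v),
                                                       n = length(v))))
  summ$condition <- rownames(summ)
  out <- list(table = tab, summary = summ, configHash = configHash(config))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(outDir, "periods.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summ, file.path(outDir, "periods_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}

# Render one axon and score its 1 um tiles against the template.
scoreSimulatedAxon <- function(imagingCfg, expansion, axonCfg, scoringCfg,
                               seed, ringDropoutP = 0, phaseJitterSdNm = 0) {
  im <- imagingFromConfig(imagingCfg, seed)
  gt <- straightAxon(scoringCfg$axonLengthNm, im, expansion,
                     extraMarginNm = scoringCfg$sizeNm * expansion@factor / 2,
                     periodNm = axonCfg$periodNm,
                     ringSigmaNm = axonCfg$ringSigmaNm,
                     axonWidthNm = axonCfg$axonWidthNm,
                     amplitude = axonCfg$amplitude,
                     background = axonCfg$background,
                     ringDropoutP = ringDropoutP,
                     phaseJitterSdNm = phaseJitterSdNm)
  ren <- renderDegradedAxon(gt, im, expansion)
  f <- expansion@factor
  tiles <- tileAxon(ren$image, ren$groundTruth@centerline,
                    sizeNm = scoringCfg$sizeNm, factor = f)
  spec <- MpsTemplate(periodNm = axonCfg$periodNm,
                      stripeSigmaNm = fwhmToSigma(im@psfFwhmNm / f),
                      sizeNm = scoringCfg$sizeNm,
                      pixelSizeNm = im@pixelSizeNm)
  scoreSegments(tiles, spec, factor = f)
}

#' Run the regularity / abundance study
#'
#' Scores simulated pristine axons under expanded-widefield (effective
#' ~77 nm) and STED-like (~90 nm) imaging, plus a degraded-lattice group
#' (ring dropout and positional jitter emulating trophic-factor-withdrawal
#' remodeling) under the expanded condition. Reports per-group score tables,
#' abundance at the configured threshold, and descriptive two-sample t-tests
#' (expanded vs STED-like; pristine vs degraded).
#'
#' @inheritParams runCalibrationStudy
#' @return list with \code{scores} (named list of data.frames),
#'   \code{abundance} (named list of \linkS4class{AbundanceResult}),
#'   \code{tests} (named list of htest) and \code{configHash}.
#' @export
runRegularityStudy <- function(config = defaultRunConfig(), outDir = NULL) {
  sc <- config$scoring
  ax <- config$axon
  nAx <- sc$nAxonsPerGroup
  fP <- config$expansion$factorProtein

  group <- function(imagingCfg, expansion, kSeed, dropout = 0, jitter = 0) {
    do.call(rbind, lapply(seq_len(nAx), function(i)
      scoreSimulatedAxon(imagingCfg, expansion, ax, sc,
                         childSeed(config$seed, kSeed + i),
                         ringDropoutP = dropout, phaseJitterSdNm = jitter)))
  }
  scores <- list(
    exm = group(config$imaging$widefield, ExpansionSpec(fP), 400L),
    sted = group(config$imaging$sted, ExpansionSpec(1), 500L),
    degraded = group(config$imaging$widefield, ExpansionSpec(fP), 600L,
                     dropout = sc$degraded$ringDropoutP,
                     jitter = sc$degraded$phaseJitterSdNm))
  ab <- lapply(scores, abundanceResult, threshold = sc$threshold)
  tests <- list(
    exm_vs_sted = stats::t.test(scores$exm$correlation,
                                scores$sted$correlation),
    pristine_vs_degraded = stats::t.test(scores$exm$correlation,
                                         scores$degraded$correlation))
  out <- list(scores = scores, abundance = ab, tests = tests,
              configHash = configHash(config))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (g in names(scores)) {
      utils::write.csv(scores[[g]],
                       file.path(outDir, sprintf("scores_%s.csv", g)),
                       row.names = FALSE, quote = FALSE)
      writeScoreHistogramCsv(scores[[g]],
                             file.path(outDir, sprintf("hist_%s.csv", g)))
    }
    jsonlite::write_json(
      c(list(config_hash = out$configHash),
        lapply(ab, function(a) list(abundance = mpsAbundance(a),
                                    threshold = a@threshold,
                                    n_total = a@nTotal, n_above = a@nAbove,
                                    n_undefined = a@nUndefined))),
      file.path(outDir, "abundance.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
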