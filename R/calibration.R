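# Expansion-factor calibration: ratio of population means per experiment,
# unweighted pooling across experiments. The estimator deliberately does not
# pair items — pre- and post-expansion populations are different objects
# (different cells, remeasured gels), so only population means are
# comparable.

#' Expansion factor of one experiment from paired populations
#'
#' The estimator is the ratio of population means,
#' \code{mean(post) / mean(pre)}, computed per experiment. Used both for the
#' macroscopic gel block (Ex-factor-Gel) and for intracellular protein
#' structures such as the perinuclear microtubule network
#' (Ex-factor-Protein).
#'
#' @param pre,post \linkS4class{MeasurementPopulation} objects with stages
#'   \code{"pre"} and \code{"post"}, same structure label.
#' @return A \linkS4class{CalibrationResult} for the single experiment (its
#'   \code{sd} slot is 0, with a warning, since one experiment carries no
#'   between-experiment dispersion).
#' @examples
#' pre <- MeasurementPopulation(c(10, 12, 11), "pre", "gel")
#' post <- MeasurementPopulation(c(40, 48, 44), "post", "gel")
#' exFactor(expansionFactor(pre, post))  # 4
#' @export
expansionFactor <- function(pre, post) {
  stopifnot(is(pre, "MeasurementPopulation"), is(post, "MeasurementPopulation"))
  if (pre@stage != "pre" || post@stage != "post")
    stop("populations must be given in (pre, post) order with matching stages")
  if (pre@structure != post@structure)
    stop("cannot compare structures '", pre@structure, "' and '",
         post@structure, "'")
  if (pre@experimentId != post@experimentId)
    stop("pre and post populations come from different experiments ('",
         pre@experimentId, "' vs '", post@experimentId, "')")
  fac <- mean(post@lengthsNm) / mean(pre@lengthsNm)
  new("CalibrationResult", factor = fac,
      perExperiment = data.frame(experiment_id = pre@experimentId,
                                 factor = fac, stringsAsFactors = FALSE),
      sd = 0, structure = pre@structure)
}

#' Pool per-experiment calibration results
#'
#' The pooled factor is the unweighted mean of the per-experiment factors and
#' the dispersion is their sample SD, mirroring how repeated expansion
#' experiments are reported (mean +/- SD over experiments).
#'
#' @param results list of \linkS4class{CalibrationResult} objects sharing one
#'   structure label.
#' @return A pooled \linkS4class{CalibrationResult}.
#' @examples
#' res <- lapply(1:3, function(i) expansionFactor(
#'   MeasurementPopulation(10, "pre", "gel", paste0("e", i)),
#'   MeasurementPopulation(10 * c(3.5, 3.6, 3.6)[i], "post", "gel",
#'                         paste0("e", i))))
#' poolExperiments(res)
#' @export
poolExperiments <- function(results) {
  if (length(results) < 1L) stop("at least one experiment is required")
  stopifnot(all(vapply(results, is, logical(1), "CalibrationResult")))
  structs <- unique(vapply(results, function(r) r@structure, character(1)))
  if (length(structs) != 1L)
    stop("cannot pool mixed structures: ", paste(structs, collapse = ", "))
  per <- do.call(rbind, lapply(results, function(r) r@perExperiment))
  rownames(per) <- NULL
  facs <- per$factor
  sdv <- if (length(facs) > 1L) stats::sd(facs) else {
    warning("single experiment: between-experiment SD undefined, reported as 0")
    0
  }
  new("CalibrationResult", factor = mean(facs), perExperiment = per,
      sd = sdv, structure = structs)
}

#' Expected lateral resolution after expansion
#'
#' Physical expansion improves the effective resolution linearly: an optical
#' FWHM of 360.51 nm at expansion factor 4.68 images pre-expansion structure
#' at an effective 77.03 nm.
#'
#' @param fwhmNm optical lateral resolution (FWHM, nm) of the microscope.
#' @param factor linear expansion factor (>= 1).
#' @return effective pre-expansion-space resolution in nm,
#'   \code{fwhmNm / factor}.
#' @examples
#' expectedResolution(360.51, 4.68)  # 77.03
#' @export
expectedResolution <- function(fwhmNm, factor) {
  if (!is.numeric(fwhmNm) || fwhmNm <= 0) stop("fwhmNm must be > 0")
  if (!is.numeric(factor) || factor < 1) stop("factor must be >= 1")
  fwhmNm / factor
}

#' Relative discrepancy between gel-block and protein-structure factors
#'
#' Quantifies how much more the gel polymerized within the protein-dense cell
#' expands than the macroscopic gel block. Two statistics are returned: the
#' pooled discrepancy \code{100 * (protein - gel) / gel} computed from the
#' pooled factors, and — when the two results cover the same experiments —
#' the mean of the per-experiment paired percentage increases, which is the
#' quantity usually quoted for paired designs.
#'
#' @param gel \linkS4class{CalibrationResult} with structure \code{"gel"}.
#' @param protein \linkS4class{CalibrationResult} with structure
#'   \code{"protein-structure"}.
#' @return list with \code{pooled_pct}, and \code{paired_mean_pct} (NA when
#'   experiment sets differ).
#' @examples
#' gel <- new("CalibrationResult", factor = 3.55,
#'            perExperiment = data.frame(experiment_id = "e1", factor = 3.55),
#'            sd = 0, structure = "gel")
#' prot <- new("CalibrationResult", factor = 4.68,
#'             perExperiment = data.frame(experiment_id = "e1", factor = 4.68),
#'             sd = 0, structure = "protein-structure")
#' factorDiscrepancy(gel, prot)$pooled_pct  # 31.83
#' @export
factorDiscrepancy <- function(gel, protein) {
  stopifnot(is(gel, "CalibrationResult"), is(protein, "CalibrationResult"))
  if (gel@structure != "gel" || protein@structure != "protein-structure")
    stop("arguments must be (gel, protein-structure) calibration results")
  pooled <- 100 * (protein@factor - gel@factor) / gel@factor
  g <- gel@perExperiment; p <- protein@perExperiment
  paired <- NA_real_
  if (nrow(g) == nrow(p) && setequal(g$experiment_id, p$experiment_id)) {
    gs <- g$factor[order(g$experiment_id)]
    ps <- p$factor[order(p$experiment_id)]
    paired <- mean(100 * (ps - gs) / gs)
  } else if (nrow(g) > 1 || nrow(p) > 1) {
    stop("paired discrepancy needs matching experiment sets; got {",
         paste(g$experiment_id, collapse = ","), "} vs {",
         paste(p$experiment_id, collapse = ","), "}")
  }
  list(pooled_pct = pooled, paired_mean_pct = paired)
}

#' Calibrate a whole population table in one call
#'
#' Convenience wrapper: splits the table by experiment, estimates each
#' experiment's factor by the ratio of means, and pools.
#'
#' @param table data.frame as produced by \code{\link{samplePopulation}}.
#' @param structure \code{"gel"} or \code{"protein-structure"}.
#' @return pooled \linkS4class{CalibrationResult}.
#' @export
calibrateTable <- function(table, structure) {
  pops <- populationsFromTable(table, structure)
  poolExperiments(lapply(pops, function(p) expansionFactor(p$pre, p$post)))
}
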