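# ExMPS

Quantitative protein-retention expansion microscopy (pro-ExM) of the axonal
membrane-associated periodic skeleton (MPS), as an R package.

## The problem

The MPS — actin rings spaced by spectrin tetramers at a ~190 nm period along
axons — sits below the diffraction limit of conventional fluorescence
microscopy. Expansion microscopy makes it visible on ordinary microscopes by
physically magnifying the specimen inside a swellable hydrogel, but every
distance measured on an expanded image must be divided by the linear
expansion factor, and the gel polymerized inside the protein-dense cell
swells **more** than the macroscopic gel block. Calibrating on the gel block
(the common shortcut) therefore systematically inflates rescaled distances.
ExMPS is for microscopists and neurobiologists who want the full
quantitative chain — calibration, resolution budget, period measurement and
regularity scoring — with every stage testable against simulated ground
truth.

## What it computes

* **Expansion factors** — per experiment, `f = mean(post) / mean(pre)` over
  populations of diameters; pooled as the unweighted mean ± SD across
  experiments. Two flavours: `Ex-factor-Gel` (gel-block diameters) and
  `Ex-factor-Protein` (an intracellular structure, the perinuclear
  microtubule network), plus their percentage discrepancy.
* **Resolution** — mean FWHM of sub-diffraction bead images via 2D Gaussian
  fits (`FWHM = 2√(2 ln 2) σ`), and the expected post-expansion resolution
  `FWHM / f`.
* **MPS period** — the five-peak rule: distance from the 1st to the 5th
  consecutive intensity peak divided by 4, with prominence-based peak
  detection, sub-pixel parabolic refinement, and rescaling by the
  experiment's expansion factor.
* **Regularity / abundance** — axons tiled into 1 µm × 1 µm segments, each
  scored by the Pearson correlation `r` against a modeled periodic stripe
  pattern (phase-optimized); MPS abundance is the fraction of segments with
  `r` above a threshold (default 0.12).
* **Synthetic ground truth** — a generator that plants an MPS lattice with a
  known period, expansion factor, Gaussian PSF and Poisson + read noise, so
  parameter recovery is verifiable end to end.

## Worked example

```r
library(ExMPS)
cfg <- defaultRunConfig(seed = 1)

cal <- runCalibrationStudy(cfg)
cal$gel
#> CalibrationResult (gel): factor 3.512 +/- 0.0912 (n = 6 experiments)
cal$protein
#> CalibrationResult (protein-structure): factor 4.687 +/- 0.0772 (n = 6 experiments)
round(cal$discrepancy$pooled_pct, 1)
#> 33.5

expectedResolution(360.51, 4.68)
#> 77.03205

runPeriodStudy(cfg)$summary
#>                    mean_nm  sd_nm  n          condition
#> exm_gel_factor       250.8 1.0615 30     exm_gel_factor
#> exm_protein_factor   190.2 0.8052 30 exm_protein_factor
#> sted               189.5 2.1225 30               sted
```

Reading: populations planted at factors 3.55 (gel) and 4.68 (protein
structure) are recovered within ~1%; the cell-internal gel expands ~30% more
than the block. A 360.51 nm widefield PSF images pre-expansion structure at
an effective 77 nm after ×4.68 expansion — enough to resolve the 190 nm
lattice. The period study makes the calibration stakes concrete: the same
expanded measurements rescaled by the protein factor give 190 nm (matching
the unexpanded STED-like condition), while the gel factor inflates them to
~251 nm.

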