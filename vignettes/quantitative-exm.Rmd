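---
title: "Quantitative expansion microscopy of the axonal periodic skeleton: methods and design"
author: "ExMPS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative expansion microscopy of the axonal periodic skeleton: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ExMPS)
```

## The measurement problem

The axonal membrane-associated periodic skeleton (MPS) is a lattice of actin
rings spaced by spectrin tetramers at a characteristic ~190 nm period —
below the diffraction limit of conventional fluorescence microscopy.
Protein-retention expansion microscopy (pro-ExM) makes the lattice visible
on an ordinary widefield microscope by physically magnifying the specimen
inside a swellable hydrogel. Every quantitative statement about an expanded
image, however, passes through one number: the linear expansion factor used
to rescale measured distances back to pre-expansion dimensions.

The central quantitative subtlety is that the hydrogel polymerized inside
the protein-dense cell swells *more* than the macroscopic gel block
surrounding it. Calibrating on the gel block (the common practice) therefore
under-reports the expansion of intracellular structures and inflates every
rescaled distance. ExMPS implements both calibrations — `Ex-factor-Gel` from
gel-block diameters and `Ex-factor-Protein` from an intracellular reference
structure (the perinuclear microtubule network) — and the downstream
analyses that depend on them: five-peak period estimation of the
βII-spectrin lattice and template-correlation regularity scoring.

Because the underlying study deposited no raw images, the package pairs the
analysis chain with a synthetic-image generator that plants a known MPS
lattice, a known expansion factor and a known optical model, so every stage
can be validated against ground truth.

## Estimators

**Expansion factor.** For one experiment the estimator is the ratio of
population means, `mean(post) / mean(pre)`. Pre- and post-expansion
populations are *different* objects (cells are destroyed by the protocol;
gels are remeasured but not identified item-by-item), so no per-item pairing
is assumed. Experiments are pooled by the unweighted mean of per-experiment
factors, with their sample SD as the dispersion — the way repeated
expansion runs are conventionally reported. For log-normal diameter
populations the ratio-of-means estimator is consistent with `O(cv^2 / n)`
bias, negligible at the study's sample sizes (40 cells, CV 15%).

**Resolution.** Lateral resolution is the mean FWHM of isolated
sub-diffraction bead images, each fitted with a 2D symmetric Gaussian plus
constant background (Levenberg-Marquardt via `minpack.lm`), with
`FWHM = 2 sqrt(2 ln 2) sigma`. A 2D fit is used rather than a 1D line
profile because it uses every window pixel; for 20 nm beads under a 360 nm
PSF the finite bead size biases the FWHM by under 0.2% (variances add:
the disk contributes R²/4 per axis), which the test suite verifies by
comparing point-source and disk renders. The expected resolution after
expansion is simply `FWHM / factor` — physical magnification divides the
effective PSF.

**Period (five-peak rule).** The field measures the MPS period as the
distance from one bright spot to the fifth consecutive one, divided by
four; in expanded samples the result is further divided by the experiment's
expansion factor. The manual "bright spot" selection is automated
reproducibly:

* local maxima must have a topographic prominence of at least 20% of the
  profile's robust amplitude (95th minus 5th percentile) — rejecting noise
  wiggles without a hard intensity threshold;
* maxima closer than half the expected period are merged (the more
  prominent one wins);
* each surviving peak is refined by three-point parabolic interpolation —
  at 100 nm/px sampling, integer-pixel peaks would quantize a 190 nm period
  to ±26 nm after rescaling by 4.68;
* when more than five peaks exist, the five-consecutive window whose four
  spacings have minimal variance is taken (leftmost on ties), emulating an
  operator choosing a clean stretch.

Both the prominence fraction and the expected period are explicit
arguments. A brute-force oracle (every candidate window, best fit to a
perfect lattice) backs the implementation in the test suite.

**Regularity and abundance (template correlation).** Axons are tiled into
consecutive, non-overlapping 1 µm × 1 µm segments along the traced
centerline, each resampled by bilinear interpolation so the local tangent
is horizontal — this is how a single axial template applies to curved
axons. Each segment is scored by the Pearson correlation, over all pixels,
against a modeled pattern of transverse Gaussian stripes at 190 nm spacing,
maximized over axial phase shifts of the template in one-pixel steps across
one period. MPS abundance is the proportion of defined segments whose
correlation is strictly above a threshold (default 0.12, a configuration
value, not a constant of nature). Zero-variance segments and segments
leaving the image are excluded from the denominator and reported
separately.

Design choices the original description leaves open, fixed here as
defaults: the stripe profile is Gaussian with sigma equal to the effective
imaging resolution (matched blur maximizes sensitivity; configurable); the
correlation is phase-optimized but *not* period- or rotation-optimized
(rotation is handled by the tiling resampling); for expanded-space images
the template is stretched by the calibration factor rather than shrinking
the image, so the data are resampled only once; threshold ties are
excluded.

A known behavior of phase-optimized scoring: because the maximum over ~10
shifts is taken on segments with few effective degrees of freedom (a
handful of rings, spatially correlated pixels), completely aperiodic
segments do not score near zero — they retain a positive chance-alignment
bias, and a minority can exceed a low threshold such as 0.12. Degradation
therefore shows up as a strong *relative* drop in mean correlation and
abundance, not as abundance exactly zero.

## The synthetic generator

`renderAxon` plants rings at arc-length positions `phase + k · period`
along a centerline, drops each ring with probability `ringDropoutP`,
jitters positions with SD `phaseJitterSdNm` (both drawn in pre-expansion
space so the same seed yields exactly proportional coordinates at any
factor), scales all coordinates by the expansion factor, and renders each
surviving ring as a Gaussian-profiled transverse line element. The optics
are analytic: a Gaussian axial profile convolved with the Gaussian PSF is
again Gaussian (variances add) and a hard-edged transverse extent becomes a
difference of error functions, so expected images carry no gridded
convolution error. Noise is the standard widefield camera model — Poisson
shot noise on expected counts, then additive Gaussian read noise, clipped
at zero. `renderBeadField` renders uniform disks convolved with the PSF by
equal-area quadrature over the disk (33 points; exact to well below the
fitting tolerances at a 10 nm radius under a 150 nm sigma).

Defaults encode the study conditions: planted period 190 nm; expansion
factors 4.68 (protein structure) and 3.55 (gel); widefield PSF FWHM
360.51 nm sampled at 100 nm/px in expanded space; a STED-like reference at
90 nm FWHM and 20 nm/px; calibration populations of 6 experiments × 40
nucleus diameters (25 µm scale, CV 15%, measurement CV 2%) and 6 × 3 gel
diameters (5 mm scale, CV 3%, measurement CV 1%); 30 period measurements
per condition. No SNR or labeling-density figures were published for the
original images, so the photon-budget defaults (ring peak ~80 counts,
background 10, read noise 3) are the package's own choice, set once so that
the five-peak rule operates reliably under the study's optical conditions;
they are parameters, not reported values.

**What the generator does not emulate.** Rings are unresolved Gaussian
line elements (ExM at ~77 nm does not resolve ring substructure); axons are
single-channel, 2D, with constant labeling density; true lattice period is
exactly constant along an axon. Real axons carry biological period
dispersion (published SDs are ~10–20 nm), antibody-size offsets, uneven
labeling and local gel distortions. Passing recovery tests therefore shows
the *estimators* are unbiased and precise under the stated model, not that
real-tissue dispersion is reproduced: simulated period SDs (~1 nm) are far
below real ones, and the spatial-consistency bounds (<5%) are met with
wide margin for the same reason. One smooth sinusoidal non-isotropy field
(`distortionAmplitude`) is available for robustness experiments but
defaults to zero.

## Numerical and degenerate-input choices

* Coordinates are in nm with the origin at the image corner and pixel
  centers at `(i − 0.5) · pixelSize` (1-based indices); sampling uses
  bilinear interpolation and points outside the raster are `NA` at the
  sampler, errors (with the offending coordinate) at the profile extractor,
  and skip-with-warning at the tiler.
* The render field of view is auto-sized to the expanded centerline plus a
  margin of three PSF FWHM plus the transverse ring extent, mirrored on
  both sides; an explicit field of view that cannot hold the geometry is an
  error naming the extent.
* Every generator call takes one integer seed; per-item sub-seeds are
  derived with a fixed linear-congruential map, so renders are
  bit-reproducible and coordinate draws are shared across expansion
  factors. The caller's RNG state is saved and restored.
* A single experiment pools to SD 0 with a warning (dispersion across
  experiments is undefined); a single successful bead fit behaves the same.
* Bead fits are flagged as failed (and excluded, counted) when the
  optimizer does not converge or sigma ends on its [0.2, 5] × initial
  bounds.
* Pooled versus paired discrepancy: `(4.68 − 3.55)/3.55` ≈ 31.8% while the
  mean of per-experiment paired increases is generally a slightly different
  number; both are computed, and the paired form requires matching
  experiment sets.

## Study sizes

The bundled study runners use 6 × 40 and 6 × 3 calibration populations, 30
five-peak measurements per imaging condition, 4 × 30 measurements for each
spatial-consistency comparison, 30 beads for the resolution figure, and
~10 axons × 3 segments per regularity group — the same orders as the
original study design, and small enough that the full test suite and the
acceptance script run in seconds on one core.

## Worked example

```{r example}
cfg <- defaultRunConfig(seed = 1)
cal <- runCalibrationStudy(cfg)
cal$gel
cal$protein
cal$discrepancy$pooled_pct

per <- runPeriodStudy(cfg)
per$summary
```

The gel-factor row of the period summary shows the practical consequence of
mis-calibration: rescaling the same raw measurements by the gel-block
factor inflates the recovered period by the factor ratio
(190 × 4.68 / 3.55 ≈ 250 nm), while the protein-structure factor recovers
the planted 190 nm.

## Known limitations

* The scorer's phase-search bias (above) makes absolute abundance values
  threshold- and condition-dependent; only contrasts under a shared
  configuration are meaningful.
* The tiler requires the traced centerline plus half a segment of clearance
  inside the image; heavily curved axons whose tiles leave the image lose
  those tiles (reported, not imputed).
* Spectral (autocorrelation/Fourier) period estimation exists only as a
  test oracle; the exported estimator is deliberately the field-standard
  five-peak rule.
* 3D stacks are treated as independent planes; chromatic and multi-channel
  effects are out of scope.
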