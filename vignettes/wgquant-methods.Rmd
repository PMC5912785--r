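---
title: "Quantifying Wnt/Wingless signaling readouts: models and methods"
author: "wgquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Wnt/Wingless signaling readouts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgquant)
```

## The biological problem

In the segmented *Drosophila* embryo, Wingless (Wg, the fly Wnt) is
expressed in one cell row per segment and inhibits the Axin/APC2
destruction complex in nearby cells, letting Armadillo (Arm, the fly
β-catenin) accumulate in the cytoplasm and nucleus. Three quantitative
readouts characterise this system in images:

1. **Arm accumulation** — a graded anteroposterior (AP) profile peaking at
   the Wg stripes, measured after subtracting the junctional (adherens
   junction) pool of Arm, which holds roughly 70% of total Arm and would
   otherwise swamp the signaling pool.
2. **Destruction-complex puncta** — Axin:GFP assemblies that are bright and
   cytoplasmic in Wg-OFF cells but dimmer and membrane-proximal in Wg-ON
   cells. Their absolute GFP content is estimated by ratioing integrated
   spot intensity against yeast kinetochore-cluster standards with known
   stoichiometry: Ndc80 (306 GFP molecules) and Mif2 (58 molecules).
3. **Engrailed (En) rows** — Wg-dependent En expression spans the two most
   posterior cell rows per segment in the wild type; widening or narrowing
   of this band reports gain or loss of signaling.

Alongside the image measurements, mRNA abundances (FPKM) and immunoblot
densitometry folds are combined by simple ratio arithmetic, including a
three-way chain of blot ratios that estimates the endogenous APC2:Axin
stoichiometry (4.3 × 1.0 / 0.9 ≈ 4.8, printed as ~5-fold).

Because the original microscopy data are not redistributable, the package
ships a synthetic-image generator that emulates the statistical structure
these procedures assume, with complete ground truth, so every stage is
verified by parameter recovery rather than by eye.

## The synthetic embryo

`renderEmbryo()` builds a rectangular lattice of cells (default 20 px =
5 µm pitch at 0.25 µm/px) separated by 2-px junctional membrane lines,
three segments of six cell columns, and eight cell rows; the embryo
occupies 8 consecutive 1-µm z slices of a 12-slice stack. Four channels are
rendered: junction marker (membrane lattice), Arm, Wg (stripe-cell
cytoplasm) and GFP (puncta plus diffuse cytoplasm). All projected signal
levels are defined on the 8-µm sum projection, so the canonical projection
recovers the configured parameters directly.

Design choices worth knowing:

* **Junctional fraction.** The Arm channel is an exact sum of a junctional
  image and a cytoplasmic image. The junctional pool is normalised *per
  lattice period* (one cell column plus its left membrane line) so that
  junctional/total equals `junctionalFraction` (default 0.70) inside every
  period — hence within any period-aligned ROI and globally. A global
  normalisation alone would drift by a few percent in local ROIs, because
  the stripe profile weights cell interiors more than the membrane lines.
* **Stripe amplitude.** The cytoplasmic AP profile is base level plus
  Gaussian bumps (σ = one cell diameter) at the stripe centres.
  `armStripeAmplitude` (default 60 counts) is defined as the expected
  stripe-minus-interstripe difference of 100 × 30 px box means on the
  membrane-subtracted projection; the per-pixel gain implied by that
  definition is computed against the exact measurement geometry at render
  time. This makes "recovered amplitude" a well-defined quantity.
* **Puncta.** One punctum per cell; counts are log-normal (sdlog 0.5)
  around 260 molecules in Wg-OFF cells and 130 in Wg-ON cells, clipped to
  46–931, so the two-region mixture averages ≈195–200 molecules.
  Wg-OFF puncta sit in the cytoplasm (≥4 px from the membrane), Wg-ON
  puncta within ~2 px of a membrane line. Puncta are redrawn until ≥11 px
  apart: closer pairs are unresolvable and would not be scored as separate
  structures. Spots are 3-D Gaussians (σ<sub>xy</sub> = 1.5 px,
  σ<sub>z</sub> = 1 slice) whose integrated photon count is
  molecules × `brightnessPerMolecule`, and are axially centred on slice
  centres so the depth-of-field capture fraction is identical for embryo
  puncta and yeast standards and cancels in calibration.
* **Noise.** Poisson shot noise on signal plus background offset, additive
  Gaussian read noise (sd 2), hard clip at the 16-bit ceiling.
  `brightnessPerMolecule` defaults to 80 counts/molecule so that the
  dimmest calibration standard (58 molecules) is bright enough that shot
  noise does not perturb its half-peak z-slice selection (< 1% bias); the
  value is camera-dependent and carries no biological meaning.
* **What is not modelled:** embryo curvature, spectral bleed-through,
  learned-classifier segmentation noise, sub-slice axial offsets,
  cell-shape irregularity and per-embryo staining variability. Passing
  recovery tests therefore demonstrate correctness of the *measurement
  arithmetic* under the stated imaging model, not robustness to every
  property of real embryos.

## Membrane mask and Arm quantification

The junction channel is segmented deterministically (`segmentMembrane()`):
Gaussian smoothing (σ = 1 px), a bright-ridge filter (most negative Hessian
eigenvalue), hysteresis thresholding at 20%/5% of the maximum response,
and 3 × 3 closing. On noiseless synthetic junctions this recovers the
membrane truth at F1 ≈ 0.99; dilation is available but off by default
since widening the mask moves adjacent cytoplasmic intensity into the
membrane pool and biases the pool split upward.

`subtractMask()` zeroes masked pixels (conservation is exact);
`poolSeparation()` decomposes a background-adjusted ROI into membrane and
cytoplasmic/nuclear pools with exact intensity and area accounting. The
study's 160 × 20 px pool ROI was drawn with the anterior rotated to the
top; in this package's canonical anterior-left frame the equivalent ROI is
20 px along AP × 160 px along DV, placed by `placePoolRoi()` on one
period-aligned interstripe cell column.

Stripe/interstripe measurement (`placeStripeBoxes()`, `stripeInterstripe()`)
detects stripe centres from the Wg channel (column-sum peaks, half-max
centroid refinement) and measures 100 × 30 px boxes; the difference is
invariant to the background estimate by construction. Profiles
(`profileAcrossSegments()`) are column means, resampled to 100 points per
segment (the embryo-length adjustment) and shifted so the minimum is zero
(the simplest reading of bringing valleys to zero: one global minimum, not
per-valley baselines). An optional Gaussian smoothing of the profile at the
cell scale suppresses single-cell ripple when segment-scale structure is of
interest; it is off by default.

## Molecule counting

`detectPuncta()` finds 3-D local maxima above median + 8 robust sds with a
4-px minimum separation, then records each punctum's depth of field as the
contiguous z slices whose in-slice background-subtracted integral exceeds
half the peak slice. `integratedIntensity()` applies the nested-ROI rule:
sum over the 15 × 15 px inner ROI minus inner area × background, per slice,
summed over the punctum's slices. The background statistic over the
21 × 21 outer frame is the **median** by default: in a dense epithelium a
neighbouring punctum often overlaps a few frame pixels, which biases the
frame mean (we measured 6–9% undercounting for membrane puncta) but leaves
the median unaffected; the mean remains available via `bgStat = "mean"`.

Calibration (`measureStandard()`, `countMolecules()`) converts intensity to
molecules against both standards; a punctum is accepted when the two
estimates agree within ±15 molecules (treated as an absolute tolerance at
all count scales), and the accepted count is the arithmetic mean of the two
estimates (the combination rule is not otherwise specified). Standards and
puncta must carry the same imaging-settings id — the same-session contract.
An optional exponential distance-from-coverslip correction
(`attenuationPerUm`, default 0) is exposed but not applied by default; the
exact correction used with the original data is not reproducible from the
text. Saturated puncta (any inner-ROI pixel at the camera ceiling) are
excluded before counting, mirroring the exclusion of the brightest puncta
that exceeded the standards' linear range.

`percentileThresholdRanking()` reproduces the brightest-pixels analysis:
thresholds are intensity quantiles over foreground pixels only (the
foreground is segmented by thresholding a smoothed channel sum above the
image-border background; the specimen must not touch the border), and
per-class coverage is reported against the simulator's structure classes.
On default renders the brightest 0.1% of pixels fall inside Wg-OFF
cytoplasmic puncta, membrane puncta gain coverage by 1%, and the elevated
Wg-ON cytoplasm only appears by 15% — the expected brightness ordering.

## En rows, levels and statistics

`countEnRows()` operationalises manual cell counting: three AP-parallel
lines (midline-proximal plus two lateral, each snapped to the densest
nearby row so lines run through cell interiors), intersected with En bands
2–5 grouped from column occupancy with gap tolerance, counting connected
foreground runs separated by ≥2 px gaps. The mean over lines and bands is
exactly 2.0 on noiseless wild-type fixtures and scales with the generator's
row count.

`fpkmRatio()` and `chainFolds()` implement the ratio arithmetic. Chained
folds compose at either open end of the chain with automatic inversion;
uncertainty propagates to first order with relative sds added in
quadrature. Note that propagating the three printed blot folds
(4.3 ± 1.4, 1.0 ± 0.5, 0.9 ± 0.4) gives 4.8 ± 3.6 — a larger uncertainty
than the ±1.4 printed alongside the chained estimate, whose derivation is
not stated; the package reports the propagated value. Folds above 5 (or
below 0.2) must be marked dilution-verified or a warning is raised,
mirroring the serial-dilution rule for densitometry outside the linear
range.

The statistical battery (`pairedT()`, `unpairedT()`, `anovaDunnett()`,
`oneSampleFoldTest()`, `normalityCheck()`) is two-sided throughout (the
star conventions imply two-sided tests) and uses the classic equal-variance
unpaired t by default with Welch as an option. Dunnett comparisons go
through `multcomp::glht` on an `aov` fit. The D'Agostino–Pearson omnibus
K² is implemented directly (no installed R package provides it) and is
validated against an independent reference implementation; Shapiro–Wilk
uses `stats::shapiro.test`. Degenerate inputs (zero variance, n below a
test's minimum) are flagged rather than silently mishandled.

## Problem sizes and numerical choices

Test and acceptance runs use the default 424 × 224 × 12 stack (three
segments, 144 cells, 144 puncta per embryo): five noisy embryos give >700
counted puncta, and eight seeds are used for stripe-amplitude recovery.
The Dunnett type-I-error simulation uses 3000 replicates of 5 groups × 10
values, giving a Monte-Carlo standard error of ~0.004 on the familywise
rate. Quantiles use R's default type-7 definition; ties in peak detection
are broken toward the brighter, earlier-indexed candidate; all coordinates
are 1-based with images indexed (y, x) and stacks (z, y, x).

## Known limitations

* The lattice geometry makes membrane segmentation easier than in real
  epithelia; segmentation parameters will need retuning for real images.
* Per-punctum molecule estimates inherit a per-punctum scatter of a few
  percent from sub-pixel placement and the half-peak depth-of-field rule;
  the calibration is unbiased in the mean but individual counts are not
  exact.
* The simulator's one-punctum-per-cell rule fixes puncta density; analyses
  sensitive to density (e.g. percentile coverage values) are
  generator-specific.
* `runPipeline()` orchestrates single-embryo workflows; batch/multi-embryo
  aggregation is left to the caller.
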