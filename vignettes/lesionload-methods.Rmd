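---
title: "Methods: slice-wise lesion load and sparse lesion-symptom mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice-wise lesion load and sparse lesion-symptom mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionload)
```

This vignette is the package's account of its own methods: the models and
procedures, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

## Data model

Every volume is a 3D grid plus a 4×4 voxel-to-world affine (mm, RAS+
world axes, voxel centers at integer 0-based indices). Lesions and ROIs
are strictly binary masks; statistical maps are nonnegative real grids.
All pairwise operations require the two volumes to share a grid — equal
shapes and affines agreeing within 1e-4 mm, a tolerance far below
analysis resolution but generous to registration round-off. Volumes are
reoriented to RAS+ on load where the NIfTI header permits, so axis
conventions (x = left–right, y = posterior–anterior, z =
inferior–superior) are uniform downstream. Resampling of binary masks is
nearest-neighbour by voxel-center world coordinates; binary data are
never interpolated.

## Slice-wise ROI lesion load

The statistic answers: *how completely does a lesion transect the ROI's
cross-section, at the worst level along its course?* The ROI (here the
cerebellar outflow pathway: deep nuclei plus superior cerebellar
peduncles) is partitioned into `bin_width_mm` (default 1 mm) slices
perpendicular to an oblique coronal axis. The axis is a coronal normal
tilted by `angle_deg` about the left–right world axis,
**n** = (0, cos θ, sin θ); the default θ = 17° makes slices perpendicular
to the superior cerebellar peduncles. θ is a configuration value: the
statistic is well defined on [0°, 90°), with 0° giving pure coronal
slicing.

Two choices were open here:

* **Binning rather than resampling.** Voxel centers are projected onto
  **n** and assigned to the nearest 1 mm bin center (bins anchored at the
  minimum projection). Resampling the volumes onto a rotated grid would
  introduce interpolation artifacts on binary data; projection binning is
  exact, fast, and invariant to rigid translations applied to both
  volumes.
* **Tilt sign.** Only the magnitude of the tilt is anatomically
  specified; positive angles tilt the slice normal superiorly. The sign
  convention is configurable by supplying the complementary geometry.

Per slice *b*, the overlap percentage is
`100 · |lesion ∩ ROI ∩ b| / |ROI ∩ b|`; the lesion load is the maximum
over slices, with argmax ties broken toward the smallest bin index so
reports are deterministic. A lesion covering every ROI voxel of some
slice scores exactly 100 %; one that spares the ROI scores exactly 0 %.
Slices with very few ROI voxels can produce unstable 0/100 values;
`min_roi_voxels_per_bin` (default 1, i.e. no filtering) can drop them.
An empty ROI is rejected, not scored.

The weighted-map load treats an a-priori statistical map as voxel
weights: `raw_sum` is the total map weight under the lesion and
`normalized_load` divides by the total map weight, giving a [0, 1]
fraction. The normalization of this quantity is not uniquely pinned down
by its provenance (published values are on an arbitrary standardized
scale); the total-weight fraction was chosen because it is
scale-invariant in the map and bounded, and cohort z-scores can be formed
downstream when a standardized effect is wanted.

## Group statistics

Group comparisons use the Welch unequal-variance t-test. This choice is
forced by the arithmetic of the published degrees of freedom this package
reproduces: Satterthwaite df floored to an integer (11, 30) rather than
the pooled df (54). The p-value is computed at the exact, unfloored df;
the floored `df_report` is what conventionally appears next to t. One-
and two-tailed p-values are always both reported (the planned load
hypothesis is one-tailed, symptomatic > asymptomatic). Cohen's d uses the
pooled sample SD without small-sample correction. `welch_t()` accepts raw
samples or (n, mean, sd) summaries — the two routes agree to 1e-12, and
the raw route is checked against `stats::t.test` to 1e-10 in the test
suite.

The dose-response table bins lesion loads into half-open intervals
[e_i, e_{i+1}) with the last bin closed at 100. The default edges
{0, 1, 25, 50, 75, 100} place effectively ROI-sparing lesions (< 1 %) in
their own bin and quarter the rest; the published binning is not
specified, so the edges are configurable. Empty bins are reported with
n = 0 and a missing rate rather than being dropped.

## Lesion-symptom mapping

The mapping stage is an explicitly simplified single-component sparse
CCA between the subjects × voxels lesion matrix and the binary outcome;
the reference implementations in the field are substantially more
elaborate (multi-component, spatial penalties, cluster thresholds), and
this module's interface (`sccan_fit()` behind `lsm_map()`) is the point
where a richer implementation could be swapped in.

* Voxels lesioned in fewer than `min_coverage` subjects (default
  ⌈0.05 n⌉) are excluded: they cannot support stable association
  estimates.
* The weight vector is the soft-thresholded, nonnegative voxel–outcome
  association: gradient X′(y − ȳ) on **column-standardized** data, i.e.
  each voxel's covariance is scaled by its standard deviation. This is
  the canonical-correlation convention; without it the gradient is a raw
  covariance and the fit systematically prefers high-coverage voxels
  (those lesioned in many subjects) over strongly associated ones, which
  measurably degrades localization of a planted causal region. Columns
  with zero variance get zero weight.
* The soft threshold λ is set to the (k+1)-th largest clipped gradient,
  k = max(1, ⌊sparseness · p⌋), so the nonzero fraction never exceeds
  the requested sparseness; the vector is renormalized to unit Euclidean
  norm. A fit where no voxel has positive association is reported as
  degenerate (all-zero weights) rather than normalized.
* Because the outcome side is a single variable the fixed-point update
  converges in one step; the iteration loop (tolerance 1e-6, max 100) is
  retained for interface fidelity with alternating-update variants.

Sparseness is selected by repeated stratified holdout: default 20
repeats of 75/25 splits (both classes represented on both sides; fewer
than two subjects per class is rejected), identical splits reused across
the candidate grid {0.005, 0.01, 0.02, 0.05, 0.1, 0.2}, held-out
subjects scored by the raw projection X_test·w, Pearson correlation with
held-out outcomes averaged over repeats, ties to the sparser value. A
degenerate or constant score vector contributes correlation 0. The whole
procedure is deterministic given its seed, and the seed is restored
around every internal RNG use so library calls never perturb the
caller's RNG state.

## The synthetic generator

The generator exists so that every stage — including the full pipeline —
can be exercised against known ground truth. It emulates the
*statistical* structure the analysis assumes, not anatomy:

* **Phantom.** An ellipsoidal "cerebellum" (default semi-axes 42, 36,
  30 mm on a 96³ 1 mm grid, origin at the grid center so x = 0 is the
  midline); paired outflow tubes (radius 3 mm, half-length 18 mm,
  lateral offset ±7 mm) with axes tilted 17° from the y axis in the y–z
  plane, positioned anterosuperiorly (tube midpoints at y = 12, z = 8
  mm); and a smooth midline Gaussian "vermis" weight bump standing in
  for an a-priori lesion-symptom map. The grid and cerebellum are sized
  so the phantom cerebellum (~190 cm³) is realistically large relative
  to the lesion volume range below; in a markedly smaller phantom the
  default lesion sizes dominate the cerebellum, every lesion transects
  the tubes, and the load distribution degenerates toward 100 %.
  Construction is deterministic and validated: tubes must lie strictly
  inside the cerebellum, and slicing the tube at its own tilt angle
  yields near-constant mid-span per-slice counts — which is what makes
  the oblique slice statistic geometrically meaningful here.
* **Lesions.** Random ellipsoids with target volumes uniform on
  1,000–30,000 mm³ and mild axis anisotropy (ratios 0.6–1.4), centered
  in a posterior-inferior "tumor bed" (centers at y ≤ −6, z ≤ −6 mm;
  within the ±7 mm midline band with probability `midline_bias` = 0.7),
  intersected with the cerebellum. The target volume is held fixed while
  placement is retried (≤ 100 attempts) until the rasterized volume is
  within ±20 % of target — this keeps boundary clipping from biasing
  the cohort volume distribution. The bed/tube geometry reproduces the
  qualitative load distribution of resection cohorts: most lesions spare
  or barely graze the outflow pathway, a tail transects it.
* **Labels.** P(symptom) = logistic(β0 + β1 · true load percent), default
  β0 = −3, β1 = 0.06; under the default phantom this calibrates cohort
  symptom rates near the ~18 % observed clinically (a simulation
  calibration, not a claim about the clinical mechanism). `label_noise`
  optionally flips each label, used to stress-test recovery. Ages are a
  truncated normal (6.2 ± 3.7 years on 0.4–14) and are pure covariates.
* **Seeding.** A master seed derives per-subject seeds by a counter
  scheme (`seed + i` for lesions, `seed + n + i` for labels/ages) so
  single subjects can be regenerated. A corollary: *nearby master seeds
  share most per-subject streams*, so replicate simulations should use
  well-separated master seeds.

What the generator does **not** emulate — and hence what passing tests do
not show about clinical data: real resection-cavity shapes (ellipsoids,
not irregular cavities with tracts of edema), registration error,
inter-rater tracing variability, confounders (tumor type, hydrocephalus,
surgical approach) correlated with both location and outcome, and any
spatial correlation structure in lesion placement beyond the tumor-bed
and midline biases.

## Numerical choices and degenerate inputs

* Projection bins: nearest-bin-center assignment; at θ = 0 on a 1 mm
  grid bins coincide exactly with integer y planes.
* Ties: argmax slice → smallest bin index; map peak → lowest
  column-major linear index; sparseness selection → smaller value.
* Rejections rather than silent defaults: empty ROI, all-zero weighted
  map, all-zero map peak, grid mismatches, constant outcomes, degenerate
  affines, non-3D volumes, impossible stratification, unplaceable
  lesions (after 100 attempts).
* Affine equality tolerance 1e-4 mm; NIfTI round trips preserve grid and
  affine to well below 1e-6.

## Problem sizes in the test suite

Unit tests run on small grids (8³–20³) and a reduced 48³ phantom; the
study-scale properties (planted-region recovery across 20 replicate
cohorts of n = 60 with 10 % label noise, permutation null calibration at
n = 60, oracle equivalence over 1,000 random mask pairs) run on the
default 96³ phantom and are the package's evidence that the pipeline
localizes a causal region and is calibrated under the null. These sizes
were chosen as the smallest configurations that still exercise the
study-scale behavior.

## Known limitations

* The mapping stage is a deliberately minimal sparse CCA; it reports a
  single nonnegative component and no spatial regularization, so its
  peak can sit adjacent to a small causal structure (in the corridor of
  lesions that cover it) rather than strictly inside it — visible at
  small phantom scales.
* The slice statistic is a maximum over slices and therefore noisy for
  ROI slices with few voxels; use `min_roi_voxels_per_bin` when the ROI
  tapers.
* Registration, normalization and lesion tracing are upstream of this
  package: inputs are assumed to be on one reference grid already.
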