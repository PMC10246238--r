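# lesionload

Lesion-location analysis for post-operative cerebellar mutism syndrome
(CMS): ROI lesion-load quantification along an oblique slicing axis,
cohort lesion maps, group statistics, and a simplified sparse
canonical-correlation lesion-symptom mapping stage — plus a synthetic
phantom/cohort generator so the whole pipeline runs and is testable
without patient data.

## The scientific problem

Roughly a quarter of children undergoing cerebellar tumor resection
develop CMS (mutism and emotional lability). The anatomical hypothesis is
that risk is driven by damage to the *cerebellar outflow pathway* — the
efferent route from the deep cerebellar nuclei through the superior
cerebellar peduncles — an anatomical bottleneck where even small lesions
can disconnect the cerebellum from the forebrain. This package implements
the quantitative machinery used to test that hypothesis on cohorts of
binary lesion masks in a common reference space, for researchers doing
lesion-symptom inference on NIfTI data.

### The lesion-load statistic

Given a binary lesion mask `L` and a binary ROI `R` on the same grid, the
ROI is partitioned into 1 mm slices perpendicular to an oblique coronal
axis with normal **n** = (0, cos θ, sin θ) (θ = 17° by default, tilting
coronal planes about the left–right axis so slices are perpendicular to
the superior cerebellar peduncles). Each ROI voxel center **x** is
assigned to the slice bin nearest round((**x**·**n** − min)/w). The
lesion load is the maximum per-slice percent overlap:

    load = max_b  100 · |L ∩ R ∩ b| / |R ∩ b|

so a lesion that transects the full pathway cross-section in any slice
scores 100 %, and one that spares the pathway scores 0 %. A second,
map-weighted load treats an a-priori lesion-symptom map `W ≥ 0` as
weights: `raw = Σ_v W_v L_v`, normalized by the total map weight.

Group inference uses one-tailed Welch t-tests (Satterthwaite df; the
floored df is reported alongside the exact-df p-value) with pooled-SD
Cohen's d, symptom rates by lesion-load bin, voxelwise overlap and
proportional-subtraction maps, and a single-component nonnegative sparse
CCA (soft-thresholded, column-standardized voxel–outcome association)
with repeated stratified 75/25 cross-validation to select sparseness.

## Worked example

Simulate a 56-subject cohort on the built-in phantom (an ellipsoidal
"cerebellum" containing paired 17°-tilted outflow tubes), then run the
core analyses:

```r
library(lesionload)

phantom <- make_phantom()                      # deterministic geometry
spec    <- cohort_spec(n_subjects = 56, seed = 42)
sim     <- simulate_cohort(spec, phantom)      # masks + ground-truth table

cms_rate(sim$cohort$status)$rate
#> [1] 0.1785714

pos <- sim$cohort$status == 1
welch_t(sim$cohort$outflow_load_percent[pos],
        sim$cohort$outflow_load_percent[!pos])
#> Welch t(10) = 3.89 (exact df 10.78), p[greater] = 0.0013,
#>   p[two-tailed] = 0.002599, d = 1.76

lsm_map(sim$masks, sim$cohort$status, seed = 42)
#> <lsm_result> sparseness 0.05, cv correlation 0.469
#>   peak at world mm (-10.5, 4.5, -7.5), weight 0.056
```

The simulated cohort has a 17.9 % symptom rate; symptomatic subjects have
substantially higher outflow lesion loads (here t(10) = 3.89 one-tailed,
d = 1.76 — the synthetic effect is deliberately generated by a logistic
dose-response on the true load), and the cross-validated mapping stage
finds a weight-map peak near the midline structures driving the labels.
The dose-response view:

```r
rate_by_load_bin(sim$cohort$outflow_load_percent, sim$cohort$status)
#>   bin_lo bin_hi  n n_positive       rate
#> 1      0      1 39          2 0.05128205
#> 2      1     25  2          0 0.00000000
#> 3     25     50  3          2 0.66666667
#> 4     50     75  9          4 0.44444444
#> 5     75    100  3          2 0.66666667
```

File-driven studies use `study_config()` + `run_study()` (NIfTI lesion
directory, ROI, optional weighted map, cohort CSV → JSON report, load
table, overlap/subtraction/LSM volumes). A thin shell wrapper around the
same functions is installed at `inst/cli/lesionload`.

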