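# sdhseg

Automated segmentation and volumetric severity assessment of subdural
hematoma (SDH) in axial head CT.

Subdural hematoma — blood collecting between the dura and the brain
surface, crescent-shaped along the inner skull on CT — is one of the
most common traumatic intracranial hemorrhages, and its **total
volume** drives severity grading and treatment urgency. Volume is
rarely measured in practice because tracing a lesion through a whole
scan by hand is slow. `sdhseg` is for researchers in medical image
analysis and neurocritical-care decision support who need a fully
automated, reproducible SDH volumetry pipeline, together with a
synthetic head-phantom cohort generator so every stage can be
developed and tested without access to clinical data.

## The method

Given a CT volume in Hounsfield units, the pipeline:

1. segments the **skull** (bone threshold, largest 3D component) and
   the **intracranial space** (interior fill of closed skull rings; a
   curvature-regularized morphological front for open rings);
2. restricts attention to the **ROI band** — the intracranial shell
   within 3.2 cm of the inner skull, computed by an exact
   anisotropy-aware Euclidean distance transform;
3. partitions the band into per-slice **SLIC superpixels** and
   describes each one by 51 features: histogram statistics of a
   25 × 25 px window (including texture smoothness
   *R* = 1 − 1/(1 + σ²)), a 32-filter **Gabor bank**
   *h*(x, y) = exp(−½ [x²/σx² + y²/σy²]) · cos(2π u₀ x) at 8
   orientations × 4 wavelengths, 5 **Laplacian-of-Gaussian** scales,
   spherical **location features** (r, θ, φ and the depth r′ below the
   inner skull), and patient age. Before filtering, each slice is
   **mirror-padded** across the irregular intracranial boundary so the
   skull edge never contaminates texture. An optional branch adds 64
   convolutional encoder–decoder (U-net tap layer) activations per
   superpixel, trained with strict scan-level fold isolation;
4. classifies superpixels with a **random forest** trained on
   1:1-undersampled data under scan-stratified cross-validation;
5. repairs the thresholded mask in 3D (small-component removal, gap
   closing against the skull, continuity filtering across slices,
   anisotropic Gaussian smoothing);
6. reports volume and the **severity dichotomy** (< 25 cc
   non-hematoma/mild, ≥ 25 cc moderate/severe), plus evaluation
   statistics: Dice = 2|S∩GT| / (|S|+|GT|), recall, precision,
   specificity within the ROI, severity confusion summaries,
   volumetric regression and Bland–Altman agreement.

## Worked example

Severity statistics from a published 110-patient confusion matrix
(rows = reference, columns = computed, classes < 25 cc / ≥ 25 cc):

```r
library(sdhseg)
t3 <- severity_confusion(counts = matrix(c(24, 1, 2, 83), 2, 2))
t3$stats
#> # A tibble: 1 × 4
#>   recall_pct specificity_pct precision_pct f1_pct
#>        <dbl>           <dbl>         <dbl>  <dbl>
#> 1       98.8            92.3          97.6   98.2
```

84 of 110 reference scans are moderate/severe; 83 are recovered
(recall 98.81%), 24 of 26 mild scans are correctly left below
threshold (specificity 92.31%), and the F1 of the severe class is
98.22%.

A synthetic case and the full cross-validated phantom experiment:

```r
ph <- generate_phantom(phantom_config(
  lesions = list(lesion_spec("acute", 60, "right")), seed = 7))
ph$volume
#> <ct_volume 'phantom'>  192 x 192 x 14 voxels, spacing 1 x 1 x 5 mm
#>   HU range [-1018.1, 1016.4], age 60 y
severity_report(ph$ground_truth, ph$volume$spacing)
#> # A tibble: 1 × 3
#>   volume_cc severity        threshold_cc
#>       <dbl> <fct>                  <dbl>
#> 1      58.8 moderate/severe           25

res <- run_cohort_cv(generate_cohort(12, seed = 1),
                     pipeline_config(n_folds = 2, seed = 1))
res
#> <sdh_cv_result>  12 scans, 2 folds
#>   mean Dice pre/post: 0.909 / 0.904
#>   volume slope 1.033, bias 1.51 cc
```

The phantom's realized lesion volume (58.8 cc) lands within 5% of the
60 cc target and is graded moderate/severe. In the 12-case experiment,
every scan is segmented by a forest that never saw it (2 scan-level
folds); computed volumes regress on true volumes with slope 1.033 and
a Bland–Altman bias of 1.5 cc, i.e. volumetry is essentially unbiased,
and all 12 severity classes are assigned correctly. `res$per_scan`
holds the per-case table, `autoplot(res$agreement)` draws the
regression and Bland–Altman panels.

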