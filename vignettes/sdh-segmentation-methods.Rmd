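---
title: "Methods: automated subdural hematoma segmentation and volumetric severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated subdural hematoma segmentation and volumetric severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

Subdural hematoma (SDH) is blood collecting between the dura and the
brain surface; on axial CT it forms a crescent hugging the inner skull.
Its total volume drives severity grading (the package dichotomizes at
25 cc: below, non-hematoma/mild; at or above, moderate/severe), but
volume is rarely measured manually because tracing a lesion through a
whole scan is slow. `sdhseg` implements a fully automated pipeline:

1. **Pre-processing.** Bone is thresholded (default 300 HU) and the
   largest 3D connected component kept as the skull. The intracranial
   space is delineated per axial slice: a closed skull ring is simply
   filled; an open ring (fracture, foramen) is recovered by a
   morphological front propagation — a seed disk at the centroid of
   sub-bone tissue grows one dilation step per iteration, restricted to
   tissue intensities, with a 3×3 majority vote acting as curvature
   regularization so the front cannot squeeze through narrow gaps. This
   is the morphological counterpart of a curvature-regularized level
   set; we chose it because it is exactly reproducible, has no tuning
   beyond an iteration cap, and its failure mode (cap reached) falls
   back transparently to closing + fill.
2. **ROI band.** SDH occurs peripherally; the region of interest is the
   intracranial shell within 3.2 cm of the inner skull surface. The
   depth field is an exact anisotropic Euclidean distance: per-slice 2D
   distance transforms to the inner surface are combined across slices
   as `min_k sqrt(d2(k)^2 + (dz*Δk)^2)`, honoring the ~10× anisotropy
   between in-plane (< 1 mm) and slice (5 mm) spacing. An index-space
   distance would be wrong by an order of magnitude in z.
3. **Superpixels.** The ROI is partitioned per slice into SLIC
   superpixels (target 64 px, compactness 0.1 on HU rescaled to [0, 1]
   over a 0–100 HU brain window). Slices are processed independently:
   at 5 mm spacing, 3D supervoxels would span unrelated anatomy.
4. **Features.** Each superpixel is described by 51 hand-crafted
   features: 9 histogram statistics of a 25 × 25 px window around its
   centroid (min, max, mean, sd, superpixel mean, skewness, kurtosis,
   entropy over 32 bins of the brain window, and smoothness
   `R = 1 − 1/(1 + σ²)` on [0, 1]-rescaled intensities); 32 Gabor
   magnitudes (8 orientations × wavelengths {2, 4, 8, 16} px/cycle,
   envelope σ = 0.56 λ ≈ one octave); 5 Laplacian-of-Gaussian responses
   (σ ∈ {1, 2, 4, 8, 16} px); 4 spherical location features (radius,
   azimuth vs. midline, elevation, and depth below the inner skull);
   and patient age. Filter responses are pooled over the superpixel by
   the mean (the centroid pixel alone is noisy; the max is
   outlier-dominated). Before filtering, the skull is removed and the
   slice is **mirror-padded** across the irregular intracranial
   boundary: an outer mask grows by one dilation per iteration while an
   inner mask shrinks by one erosion, and each new ring pixel copies
   the nearest inner-mask pixel (ties broken by lowest linear index).
   Across a straight boundary this reproduces classical reflection;
   across a curved skull it keeps oriented texture filters from
   "seeing" the bone edge. Padding is computed once per slice and
   reused by every filter.
5. **Classification.** A random forest (200 trees, √p features per
   split) classifies superpixels. Negatives outnumber positives roughly
   eight-fold, so training negatives are undersampled to 1:1 with all
   positives kept. Folds are split by scan — never by superpixel — and
   stratified by lesion type and volume stratum, so no scan influences
   its own prediction and each training split sees every lesion type.
6. **Post-processing.** The 0.5-thresholded probability map is repaired
   in 3D: per-slice components under 20 px are dropped; gaps and holes
   against the skull are closed (disc radius 3 px); 26-connected 3D
   components spanning fewer than 2 slices are removed; and the mask is
   smoothed by a 3D Gaussian with σ = 1.5 mm per axis in *physical*
   units (0.3 voxel in z at 5 mm spacing) and re-thresholded at 0.5.
7. **Severity.** Volume = voxel count × voxel volume, classified at the
   25 cc boundary. Evaluation helpers compute Dice/recall/precision
   (specificity within the ROI band, where the problem actually
   lives), severity confusion statistics, volumetric regression (with
   and without intercept, since a through-origin slope is also of
   interest) and Bland-Altman bias with 1.96·sd limits.

# The deep-feature branch

A compact U-net (two encoder levels, skip connection, 64-channel tap
layer before the 1×1 sigmoid output) can be trained per fold and its
tap-layer activations pooled per superpixel as 64 extra features. The
network is implemented natively (im2col convolutions, hand-written
backpropagation, Adam, BCE + soft-Dice loss) and sized for CPU
training on small slice stacks; gradient correctness is verified
against numeric differentiation in the test suite. Fold isolation is
enforced twice: a model refuses to train on a scan of its own held-out
fold, and feature extraction refuses a scan whose fold does not match
the model. The branch is optional and off by default — the pipeline is
complete with hand-crafted features alone, and the default desk-scale
experiments do not enable it.

# What the phantom emulates — and what it does not

Clinical CT cohorts of this kind are not redistributable, so the
package ships a head phantom generator that reproduces the *structure*
the pipeline exploits:

* an ellipsoidal ~1000 HU skull shell around a 35 HU brain with a
  central CSF space (5 HU), additive 4 HU noise, a smooth 6 HU
  gray/white texture field, and dark peripheral sulcal CSF streaks.
  The sulcal component matters: an isodense (subacute, 35 HU) lesion
  is distinguishable on real CT chiefly because it effaces the sulcal
  pattern, and without such streaks no feature in the set could
  separate it from brain;
* crescentic lesions adjacent to the inner skull — an ellipsoidal
  shell sector whose thickness (and, escalating, sector and axial
  extent) is solved by bisection to hit a target volume within 5%.
  The axial half-extent scales with the cube root of the target, so
  small collections are focal rather than implausibly thin films. The
  intensity classes are acute 70 HU > brain ≈ subacute 35 HU >
  chronic 15 HU > CSF 5 HU; "mixed" lesions stack an acute layer
  against the skull over a chronic layer;
* the acquisition geometry of the emulated cohort: 5 mm slices with
  sub-millimeter in-plane pixels. The default grid is 192 × 192 at
  1 × 1 × 5 mm — the closest to the reported 0.43–0.49 mm pixels that
  is CPU-practical. This matters more than it looks: the fixed 25 px
  feature window and 64 px superpixels are calibrated to that pixel
  scale, and coarser phantoms silently change what the features see;
* a case mix in which mixed and acute collections dominate (4 and 3 of
  11 lesion cases), chronic lesions are larger (they present late in
  atrophic, elderly brains — ages are drawn accordingly) and subacute
  ones small-to-moderate (2 each). Every type appears at least twice
  so that scan-stratified 2-fold cross-validation can place each type
  on both sides of the split, which is what fold stratification by
  type is for. A lesion-free case emulates normal controls. Strata are
  bounded at 25/50/100/200 cc.

The phantom does **not** emulate gyral anatomy, beam hardening,
partial-volume averaging at 5 mm slice boundaries, midline shift or
mass effect, non-SDH pathology, or annotation noise. Consequently the
phantom problem is *easier* than the clinical one — held-out superpixel
AUC is near 0.999 against 0.98 reported clinically — and passing the
phantom experiments demonstrates that the pipeline's machinery is
correct and unbiased, not that clinical accuracy would match.

# Numerical choices and degenerate inputs

* The smoothness statistic as printed in the source literature is
  typographically garbled; we implement the standard texture smoothness
  `R = 1 − 1/(1 + σ²)` on [0, 1]-rescaled intensities, which matches
  the stated name and limiting behavior (0 for constant patches,
  increasing in σ).
* Skewness and kurtosis of a constant window are defined as 0 rather
  than NaN; any non-finite feature elsewhere is a hard error naming
  the feature and superpixel.
* Histogram entropy uses 32 bins over the 0–100 HU brain window.
* Mirror-pad donor ties break to the lowest linear index; SLIC is
  seeded on a fixed grid; fold assignment, undersampling, forest
  training and phantom synthesis are all seeded — two runs with one
  seed are bit-identical.
* The midline for the azimuth feature is the in-plane principal axis
  of the intracranial mask on the origin slice (the first slice whose
  intracranial area reaches 100 px), not a fixed left-right axis, so a
  tilted head does not bias the azimuth. The origin is the skull's
  center of mass on that slice.
* A superpixel whose centroid falls outside the intracranial mask
  (possible for crescent-shaped regions) snaps to its nearest member
  pixel before window extraction.
* Feature slices are embedded in a canvas expanded by the pad width so
  that neither the padding ring nor a 25 px window can run off the
  array for any head geometry; if the inner mask empties before the
  pad width is reached (very small heads), the last nonempty mask
  donates, with a warning.
* Morphological closing operates on a zero-padded canvas to avoid the
  border artifact where dilated pixels at the array edge escape the
  erosion.

# Problem sizes

The default experiment — also what `scripts/acceptance.R` runs — is a
12-case phantom cohort at 192 × 192 × 14 voxels with 2-fold
scan-stratified cross-validation and hand-crafted features only:
roughly 2,100 superpixels per scan, 26,000 feature rows, and a few
minutes on one CPU. Unit tests use 64 × 64 × 6 phantoms at 2 mm
in-plane spacing, where the coarser feature scale is acceptable
because they exercise contracts, not accuracy.

# Known limitations

* Subacute detection rests entirely on textural homogeneity against
  the sulcal pattern; the smallest subacute lesions (< 10 cc) are
  fragmented or missed, mirroring the weak mild-lesion performance
  reported clinically. Post-processing can delete genuine single-slice
  fragments of such lesions (the 3D continuity rule cannot tell them
  from noise), which is the main cost of the repair chain on otherwise
  clean masks.
* The 2D DICOM reader supports uncompressed implicit/explicit VR
  little-endian single-frame CT only; enhanced multi-frame DICOM and
  compressed transfer syntaxes are rejected.
* The level-set-style front propagation assumes air outside the skull;
  an open ring adjoining soft tissue (e.g. orbital contents) bounds
  the leak only by the curvature rule.
* Volume strata above ~230 cc are geometrically infeasible in the
  default phantom head and raise an error rather than silently
  shrinking the lesion.
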