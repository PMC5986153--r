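---
title: "Methods: graph-based retinal layer segmentation and structural phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based retinal layer segmentation and structural phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`octretina` turns an SD-OCT volume (a stack of B-scans) into a clinical
phenotype in three stages:

1. **Segmentation** of the twelve retinal layer boundaries per B-scan by
   shortest-path search over a graph of Canny edge-pixel groups, followed by
   a cross-B-scan consistency correction.
2. **Feature extraction**: ten scalar features per eye — the volumes of
   hyper-reflective intra-retinal spots (HIS) and drusen, the curviness of
   the MZ-EZ and OPL-ONL boundaries, and mean / 70th-percentile thickness of
   the retina, the EZ-to-RBC complex and the RPE layer.
3. **Classification** of eyes into normal / AMD / DME with a repeated
   stratified k-fold protocol (k = 15, 10 repetitions, per-fold tuning).

A phantom generator supplies volumes with exactly known geometry; every
stage is validated against that ground truth.

## The segmentation model

Healthy retinal boundaries are smooth, near-horizontal curves of consistent
contrast polarity.  Each boundary is found as the minimum-cost path from a
virtual source (column −1) to a virtual sink (column `width`) through pixel
groups: 8-connected chains of Canny edge pixels whose axial gradient sign
matches the boundary's polarity (e.g. MZ-EZ is dark-above/bright-below).
An edge from group A to group B costs

```
w_d * |gap|  +  w_s * |slope(gap) − slope(reference)|  +  w_a * nonassoc(B) + w_p * rowpref(B)
```

with `|gap|` the Euclidean distance between A's right end pixel and B's left
end pixel; traversal within a group is free.  `nonassoc` is the group's
gradient-strength deficiency relative to the strongest group in the region
of interest (ROI); `rowpref` prefers the topmost candidate for the inner
limiting membrane (ILM-RNFL) and the bottommost for the retina/choroid
interface (RBC), the two anchors detected first.  Group-level penalties are
scaled by the group's column coverage so that a boundary fragmented into
many short chains pays the same total penalty as one long chain.

Boundaries are detected in a fixed high-to-low-contrast order.  After the
two anchors, each remaining boundary searches a per-column ROI centred on
its nominal anatomical depth fraction between the local ILM-RNFL and RBC
positions (tolerance 12% of the local retinal depth, at least 4 px),
intersected with margins around already-found neighbours.  Because the ROI
is anchored per column, drusen-elevated photoreceptor boundaries keep a
valid search band over the bump.

Numerical choices that matter:

* **Canny**: Gaussian sigma 1.5 px; hysteresis thresholds are the 70th/90th
  percentiles of the gradient magnitudes of the polarity-matching pixels
  *inside the current ROI*.  Whole-B-scan thresholds would discard the faint
  interfaces (boundary contrast spans a factor of about five) before their
  dedicated search begins.
* **Vertical-run grouping**: on steep segments non-maximum suppression keeps
  2–3 pixels per column; chaining vertical runs (runs in adjacent columns
  connect when within one row) keeps a curved boundary one chain instead of
  shattering it at pixel-level junctions.  The per-column ridge pixel is
  used for positions.
* **Sub-pixel refinement**: the gradient ridge of a step edge sits half a
  pixel above the first pixel of the layer below (the position convention);
  a parabolic fit across the ridge plus a +0.5 px offset recovers the
  convention exactly and removes the one-pixel quantisation of tie-broken
  ridges.
* **Edge weights**: `w_d = 1`, `w_s = 0.5`, `w_a = 5`, `w_p = 10`.  The
  small slope weight is deliberate: OCT voxels are anisotropic (axial
  ≈ 3.9 µm vs lateral ≈ 11.6 µm), so real drusen shoulders are steep in
  pixel units and must not cost more than skipping the bump.
* **Curve fit**: per-column mean ridge rows, linear interpolation across
  gaps, then a cubic smoothing spline with GCV-chosen smoothness.
* **Cross-B-scan correction**: a position deviating more than 5 px from the
  median over the adjacent B-scan window is replaced by that median; the
  correction is computed from the input everywhere, so it is idempotent on
  consistent sets.
* A boundary with no edge evidence in a B-scan is copied from the nearest
  B-scan where it was found (with a warning); the anatomical depth order is
  enforced at the end.

## The ten features

* **HIS volume** (mm³): pixels between the IPL-INL and ONL-ELM boundaries
  brighter than the pooled mean intensity of the RNFL and RPE bands of the
  whole volume, times the voxel volume.  The threshold is pooled per volume
  (not per B-scan) for robustness at this scale.
* **Drusen volume** (mm³): Bruch's membrane (BM) is estimated per B-scan as
  a robust line fit to the RBC boundary (columns where RBC rises above a
  first fit by more than 3 px are dropped, then refit).  The ELM-to-BM
  thickness profile is fit with a first-order polynomial; columns exceeding
  the fit by more than 3 px form candidate runs.  A run is confirmed when
  the mean intensity of the 3 px just above the detached RBC (bright RPE)
  exceeds 1.3× the mean of the 3 px just above the BM baseline
  (hypo-reflective interior).  Confirmed runs are extended to the full
  contiguous extent of the detachment (RBC above baseline), and the mask is
  all pixels between the detached RBC and the baseline — detection uses the
  strict threshold, delineation the full support.
* **Curviness** of MZ-EZ and OPL-ONL: with `NL = RBC − boundary`, the score
  is `C1 × C2` where `C1` sums the absolute deviations of `NL` from its
  first-order fit that exceed `alpha = 3` px, and `C2` counts local maxima
  surviving the pruning of adjacent extrema pairs closer than
  `delta = 5` px (smallest pair first, leftmost on ties).  Endpoints are
  eligible extrema (a monotone ramp has one max and one min) and plateaus
  collapse to their first index.  The per-B-scan scores are averaged over
  the volume.  Note that because `NL` is measured against RBC, a drusen
  eye's bumpy RBC also makes an otherwise flat OPL-ONL "curvy"; this is a
  property of the definition, not a bug, and the classifier sees both
  curviness features together with the pathology volumes.
* **Thickness statistics** (µm): per-A-scan boundary differences
  (retina = ILM-RNFL→RBC, complex = MZ-EZ→RBC, RPE = IZ-RPE→RBC) converted
  with the axial scale, smoothed with a sigma = 2 sample 2-D Gaussian over
  the A-scan × B-scan grid (border-renormalised), then summarised by the
  mean and the 70th percentile (linear interpolation between closest ranks,
  `h = (n−1)·0.7 + 1`).  The complex's upper boundary is MZ-EZ
  (config-overridable).  Micrometres were chosen over pixels so values
  transfer across devices.

## The classification harness

Eight algorithms are registered: random forest (bagged Gini CART with
`mtry = ⌊√p⌋`, grown in compiled code; tree count tuned over
{50, 100, 200, 500}), logistic regression (ridge-stabilised multinomial),
linear and RBF least-squares SVMs (kernel ridge with bias, one-vs-rest;
kernel scale tuned over a log grid — a least-squares SVM stands in for the
hinge-loss SVM because no QP solver is available in the target
environment), SAMME AdaBoost on stumps, Gaussian naive Bayes, and single
classification / regression trees.

Evaluation: per repetition a fresh stratified fold assignment (per-class
round-robin after shuffling, so fold sizes differ by at most one; with 15
eyes per class and k = 15 every test fold holds exactly one eye of each
class).  Within a fold, hyperparameters are tuned on an inner stratified
80/20 split of the training folds (ties prefer the smaller model: fewest
trees, largest kernel scale), the model is refit on the whole training
side, and the held-out fold is predicted.  Metrics are pooled per
repetition and aggregated as mean (SD) over the 10 repetitions.  Binary
mode collapses non-normal labels into "diseased" (the positive class);
three-class mode reports accuracy and one-vs-rest AUC per class with the
macro average, leaving sensitivity/specificity/f1 `NA`.  All randomness
derives from one master seed, and forests are prefix-stable in the tree
count, so runs are bit-reproducible.

## The phantom world

A phantom is a piecewise-constant layer stack (defaults: 128 A-scans ×
256 depth px × 9 B-scans, voxels 3.9 × 11.6 × 120 µm — Spectralis-like
values, since no acquisition geometry is prescribed for the public sets).
Layer intensities follow the qualitative reflectivity profile of a healthy
macular B-scan, graded so that every interface is the strongest edge of its
polarity inside its search ROI.  Pathology:

* **Drusen**: semi-elliptic sub-RPE elevations.  RBC and IZ-RPE carry the
  full bump; EZ-OSL, MZ-EZ, ELM-MZ and ONL-ELM are damped to 0.8/0.7/0.6/
  0.5 of it — the retina drapes and the outer nuclear layer thins, which
  also makes the ELM-to-BM span grow over a druse (the signal the drusen
  detector uses).  The interior matches choroid reflectivity (darker than
  the RPE), so no spurious BM edge competes with the elevated RPE bottom.
  Bump heights of 12–20 px (≈ 47–78 µm) and radii of 10–18 A-scans
  (≈ 120–210 µm) are typical soft-drusen dimensions.
* **HIS**: bright discs (radius 2–3 px, intensity ≈ 205) in the INL–ONL
  band of scattered B-scans.
* **DME archetype** additionally thickens the outer retina by ≈ 11 px
  (≈ 43 µm) and gives OPL-ONL a sinusoidal wave (amplitude ≈ 6 px, period
  ≈ 32 A-scans) emulating cyst-driven distortion.
* **Noise**: additive Gaussian, default SD 8 of 255, clipped; speckle is
  deliberately not simulated — the segmentation needs no denoising and a
  multiplicative speckle model would not change what a green test
  establishes (recovery of known geometry), only its difficulty.

Cohort jitter draws per-volume depth shifts (±3 px), per-layer intensity
offsets (±5), bump/spot geometry and wave phase from uniform ranges around
the class templates.  What the phantoms do **not** emulate: speckle
statistics, vessel shadows, motion artefacts, foveal pit geometry, real
drusen shape variety and real cyst appearance.  A green end-to-end test
therefore establishes that the pipeline recovers the stated geometry and
separates the stated archetypes — not clinical performance.

## Known limitations

* The exact edge-weight terms, reference-line construction and Canny
  settings of the original segmentation method are not published in the
  source describing this pipeline; the realisations here are reconstructions
  tuned on phantoms and exposed in `segmentation_config()`.
* Curviness against an elevated RBC conflates drusen deformation with
  boundary waviness (see above).
* The drusen detector assumes a single dominant BM line per B-scan (a
  first-order polynomial baseline); pathologies that tilt or fold Bruch's
  membrane are out of scope.
* The least-squares SVMs approximate, but are not identical to, hinge-loss
  SVMs.
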