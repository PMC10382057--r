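---
title: "Multi-contrast breast-MRI radiomics on synthetic phantom cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-contrast breast-MRI radiomics on synthetic phantom cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

`phantomics` implements a complete radiomic characterization pipeline for
breast tumors imaged in three co-registered MR contrast channels: a
dynamic contrast-enhanced T1-weighted volume (DCE), the contrast
subtraction image (Sub = DCE − pre-contrast T1, clipped at zero), and a
T2-weighted volume (T2). Per tumor and channel it computes a fixed
342-feature radiomic vector; reduces dimension with ReliefF (top 32
features) or LASSO at a relaxed penalty (retaining over one hundred
features); and trains either a linear support vector machine or a
five-layer fully connected network (FCNN) to predict binary
immunohistochemical markers (ER, PR, HER2) or histological subtype
(invasive ductal vs. invasive lobular carcinoma), reporting AUROC.

The evaluation protocol is patient-wise throughout. Patients are split
into five folds (all tumors of a patient share a fold). For each choice
of test fold, z-score normalization and the dimension reduction are
fitted on the remaining train+validation tumors only and frozen; 25
candidate models are trained on seeded 75/25 patient-wise
train/validation resamples; the candidate with the best validation AUC
is evaluated once on the test fold; results are averaged over the five
fold cycles. These guards (frozen normalization/selection, patient-wise
disjointness) are asserted at run time and re-checked by
`audit_leakage()`.

Clinical breast-MRI cohorts with linked IHC labels are essentially never
shareable, so the package ships a synthetic phantom-cohort generator
that emulates the statistical structure the analysis assumes. Every
result the tests and the acceptance script assert is computed on these
phantoms; nothing in this vignette refers to values the package does not
itself compute.

## The phantom model

A tumor is a perturbed superellipsoid: radii are drawn with mild
log-normal anisotropy around half the target size, the exponent varies
in [1.8, 2.6], and the boundary radius is modulated by a random
low-order spherical-harmonic field scaled by `shape_irregularity`
(0–1). Because the perturbation keeps the region star-shaped, masks are
always connected. The realized mean bounding-box extent is calibrated to
the target size by up to three rescaling passes; at the default 2 mm
voxels the realized size of mid-sized tumors lands within 10% of target
(sub-voxel targets floor at a single voxel and are removed by the <5 mm
exclusion anyway).

Channel intensities are background plus Gaussian noise, with an in-mask
elevation (DCE tumors always enhance) and an interior texture field: a
stationary Gaussian random field obtained by frequency-domain smoothing
of white noise, with correlation length `texture_granularity_mm` and
amplitude `texture_sd`. The texture field is the carrier of class
signal: a `class_effect_profile` maps each positive label (ER+, PR+,
HER2+, ILC) to parameter shifts scaled by a single `effect_size`;
`effect_size = 0` makes the cohort class-exchangeable by construction,
which is what the null-calibration tests rely on. T2 is synthesized on
its own coarser native grid (default 24³ at 3 mm vs. the 36³/2 mm
reference grid) and resampled onto the DCE grid during preprocessing,
exercising the same resampling path a real multi-sequence study needs.

Tumor sizes follow a log-normal law with `meanlog = log(20.3)` and
`sdlog = sqrt(2 log(24.6/20.3))`, i.e. median 20.3 mm and mean 24.6 mm —
the right-skewed distribution typical of diagnosis-time breast tumors
(the implied SD, ≈16.8 mm, is close to the clinical 16.6 mm). About a
third of patients carry a second tumor, reproducing the ≈429 tumors per
323 patients scale, and a configurable fraction of label cells is set
missing, so per-task sample sizes differ as they do in practice.

What the phantoms do **not** emulate: MR physics (no k-space, coil,
bias-field or kinetic modeling), scanner heterogeneity, segmentation
error correlated with image content, and any real biological link
between texture and receptor status. Passing tests therefore demonstrate
that the pipeline is correct, calibrated, and able to recover signal of
the injected kind — not that the biological classification problem is
solvable at any particular AUC.

## The 342-feature inventory

The feature list is defined by a YAML manifest
(`inst/extdata/feature_manifest.yaml`) and `feature_inventory()`
enumerates it; the default configuration has exactly 342 named features
in ten categories:

| category | count | construction |
|---|---|---|
| conventional | 31 | 14 shape (volume, surface area, sphericity, compactness, bounding box, elongation/flatness, maximum diameter) + 17 first-order intensity statistics |
| moments | 20 | 16 scale-normalized central moments (orders 2–3) + 3 second-moment invariants + anisotropy |
| transforms | 32 | one-level 3D Haar decomposition, 8 bands × 4 statistics |
| descriptor | 16 | rotation-invariant uniform LBP (8 neighbors), slice-wise |
| gabor | 40 | 5 frequencies × 4 orientations × {mean, sd} of slice-wise response magnitude |
| frequency | 40 | 20 radial 3D-FFT bands × {energy fraction, log mean power} |
| glcm | 84 | 28 co-occurrence statistics × distances {1, 2, 3} voxels |
| glrlm | 32 | 16 run-length statistics × {3D 13-direction, 2D in-plane} |
| glszm | 32 | 16 size-zone statistics × {26-connected 3D, 8-connected 2D} |
| ngtdm | 15 | 5 gray-tone-difference statistics × neighborhood half-widths {1, 2, 3} |

Counts follow the natural sizes of the standard feature families rather
than an arbitrary padding to a round number; the multi-distance
co-occurrence block (84) keeps the gray-level matrix features the
dominant block, as is typical of radiomic inventories of this size. The
manifest is configuration, not code: alternative counts change the
inventory and every downstream shape consistently.

The four matrix-based categories are quantization-dependent: each
feature is computed at six gray-level quantizations (8, 16, 24, 32, 48,
64 equal-width bins of the in-mask intensity range) and arithmetically
averaged. All other features are computed once — averaging a
quantization-independent value over six identical copies would be a
no-op, so this is the efficient reading of "extract at six levels and
average". Averaged texture features are consequently invariant to
intensity shifts (binning uses the in-mask min/max), which is asserted
as a property test.

## Numerical choices and degenerate inputs

* Texture-matrix kernels (co-occurrence, run length, size zones,
  gray-tone difference) are compiled code, verified against brute-force
  R enumeration on small random volumes to 1e-10.
* Entropies use log base 2 with 0·log 0 ≡ 0. Degenerate cases take
  finite documented limits instead of NaN: zero-variance co-occurrence
  correlation ≡ 0, empty run/zone matrices give all-zero features,
  NGTDM busyness/strength with zero denominator ≡ 0, and coarseness of
  a perfectly flat region caps at 1e6.
* Surface area uses the coarea estimator (integral of the gradient
  magnitude of a Gaussian-smoothed indicator), which converges to the
  true area where naive voxel-face counting overestimates a sphere by
  ~50%; digital-ball tests bound the error.
* Gabor filters are defined in the frequency domain as analytic
  single-bump transfer functions with one-octave bandwidth and their DC
  gain forced to zero (constant images give exactly zero response); the
  FFT path is verified against a direct circular-convolution oracle.
* Resampling is trilinear for intensities (exactly reproducing linear
  fields) and nearest-neighbor for masks, with constant extrapolation
  beyond the outermost voxel centers; grids share a corner origin.
* Mask smoothing is opening-then-closing with a 3×3×3 cube; a mask
  emptied by opening raises a typed degenerate-mask condition that
  cohort extraction converts into a logged exclusion.
* Quantization ties at the top bin are capped at level L; constant
  regions map to level 1 and carry a degeneracy flag.

## Classifiers

The linear SVM is an L2-slack (squared-hinge) formulation minimized by
BFGS with a negligible ridge term (λ = 1e-6), i.e. effectively
unregularized: on separable data the minimum-norm zero-loss solution is
the max-margin hyperplane (verified against the analytic solution on a
four-point problem), and on inseparable data it is a pure
slack-minimizing hyperplane. This smooth convex formulation was chosen
because classical SMO solvers do not terminate reliably at
near-infinite cost on noise-level data, while the protocol needs
thousands of deterministic fits.

The FCNN is the fixed 50-40-30-20-10 ReLU architecture with a sigmoid
output, trained full-batch with binary cross-entropy and Adam
(lr 1e-3, β = 0.9/0.999), an epoch budget of 200 and early stopping on
validation loss with patience 20 (best-epoch weights restored). Training
is a pure function of (data, seed). The budget and patience are exposed
as `run_protocol(fcnn_epochs =, fcnn_patience =)`; calibration-style
experiments in the test suite use a reduced budget, which is valid
because the chance-level property of a null cohort does not depend on
how long the network trains.

Model selection uses validation AUC (the pipeline's sole reported
metric); ties break to the lowest split index for determinism. Folds
whose test labels are single-class record `NA` and are excluded from the
fold mean with a warning. The positive class is scored high: ER+, PR+,
HER2+, and ILC.

## Dimension reduction

ReliefF is the deterministic all-rows variant: every row is an anchor;
its k = 10 nearest hits and misses (Euclidean distance on the z-scored
features) update the weights by the standard
`+|x−miss|/(m·k) − |x−hit|/(m·k)` rule; the top 32 features are kept,
ties broken by inventory order. k is reduced with a warning when a class
is too small.

LASSO selection fits the ±1 labels by L1-penalized least squares along a
100-point log-spaced path from λ_max down to 1e-3·λ_max (glmnet
coordinate descent) and keeps the largest λ whose active set exceeds 100
features. Because a LASSO active set cannot much exceed the row count,
this "over one hundred" rule is only attainable on clinical-scale folds
(hundreds of tumors); on deliberately small phantom cohorts the selector
falls back to the largest active set on the path with a warning — the
behavior, not a silent degradation. Orthonormal-design tests pin the
active set to the soft-threshold closed form.

Multi-contrast input concatenates the per-contrast feature tables
column-wise with contrast-prefixed names *before* normalization and
reduction, so the selector is free to mix channels.

## Problem sizes used by the tests and the acceptance script

Cohort sizes are scaled to single-CPU desk hardware; they are the
package's chosen study conditions, stated here for reproducibility:

* Null calibration: cohorts of 80 patients (~105 tumors), DCE-only
  designs, all four tasks × four method combinations; 8 cohorts in the
  test suite, 6 in the acceptance script. The FCNN budget is reduced to
  20 epochs / patience 3 here: the chance-level property of a
  class-exchangeable cohort does not depend on training length, and the
  per-combination acceptance band needs fold counts that a full budget
  would make needlessly slow.
* ER signal recovery: `er_texture_profile()` (granularity +3 mm,
  texture amplitude +10, all channels, ER prevalence 0.5), cohorts of
  45 patients, ReliefF+SVM on DCE+Sub+T2; 6 cohorts in tests, 5 in the
  script.
* Channel-specific effect: the same profile restricted to T2 with
  granularity +4 mm and amplitude +15 (the coarser native T2 grid
  attenuates texture contrast, so the channel-restricted scenario uses
  a stronger injection to remain "strong"); cohorts of 50 patients;
  mono-DCE, mono-T2, Sub+T2 (and the triple in tests) columns compared.
* The clinical-scale check generates one 323-patient cohort (~429
  tumors) to verify the size law and multiplicity, without feature
  extraction.

## Known limitations

* The phantom texture model is stationary and Gaussian; real lesion
  texture is neither, and phantom class effects are injected, so
  absolute AUCs on phantoms say nothing about clinical attainability.
* The feature inventory's exact composition is a documented convention
  (manifest-driven), not a standardized set; no IBSI calibration is
  claimed.
* LASSO's >100-feature rule saturates on small cohorts (see above).
* Frequency features use cycles/voxel, ignoring spacing anisotropy
  within the reference grid (isotropic by default).
* The detection-plus-classification deep-learning pathway that
  complements radiomics in large studies (region-proposal CNNs on raw
  images) is out of scope: it is GPU-scale and has no desk-scale
  verification path.
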