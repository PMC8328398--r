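---
title: "Multi-compartment OCT texture radiomics: models, parameters and design choices"
author: "octrad authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment OCT texture radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octrad)
```

## The problem

Eyes with macular edema secondary to diabetic macular edema or retinal vein
occlusion are treated with intravitreal anti-VEGF injections. When the
dosing interval is extended from four to eight weeks, some eyes tolerate
the extension ("non-rebounders") while others worsen ("rebounders"). octrad
implements a radiomics pipeline that asks whether 3D texture of the
*baseline* OCT cube — measured separately inside intraretinal fluid (IRF),
subretinal fluid (SRF) and the fluid-free retinal tissue between the inner
limiting membrane (ILM), ellipsoid zone (EZ) and retinal pigment epithelium
(RPE) — predicts that binary durability outcome, and which spatial
compartment carries the signal.

The pipeline stages are:

1. **Compartments** — from per-A-scan layer depths and binary fluid masks,
   derive four disjoint masks: IRF, SRF, RTC1 (ILM→EZ tissue minus IRF) and
   RTC2 (EZ→RPE tissue minus SRF), restricted to the mid-macular slice
   window.
2. **Texture bank** — 962 named descriptors per compartment from four
   per-voxel map families (Haralick, Laws energy, Gabor, CoLlAGe),
   aggregated over each mask by first-order statistics.
3. **Selection** — per cross-validation fold, rank features by Welch
   t-test, Wilcoxon rank-sum and mRmR; intersect the three top-15 lists and
   keep the two best by mean rank.
4. **Classification** — stratified 80:20 split, repeated stratified 3-fold
   CV inside the training split (1000 iterations at study scale), LDA, QDA,
   random forest and linear SVM on the two selected features; AUC,
   accuracy, sensitivity, specificity as mean ± sd over folds.
5. **Clustering** — PCA reduction, Ward clustergram cut, elbow-chosen
   K-means, with per-cluster class composition.
6. **Decision gate** — per-threshold percentages of correctly identified
   rebounders/non-rebounders and a target-confidence threshold search.

Because the clinical cohort this emulates is not publicly available, the
package ships a first-class synthetic cohort generator so that every stage
is exercisable and the pipeline's ability to recover a known planted effect
is testable end to end.

## Geometry and conventions

Volumes are arrays with axes (slice, depth, A-scan); depth increases away
from the vitreous. Depth intervals are half-open — `[ILM, EZ)` and
`[EZ, RPE)` — so each voxel belongs to exactly one band; boundary-voxel
ownership is a convention the source protocol leaves open. User-facing
slice indices are 1-based; the canonical mid-macular analysis window is
slices 43–85 of a 128-slice cube, rescaled proportionally for other slice
counts by mapping slice centres (`x' = (x - 0.5) n/128 + 0.5`) and rounding
the endpoints half away from the volume centre. Fluid-mode windows
additionally drop slices whose fluid masks are empty; a window left empty
raises a typed condition (`octradNoFluidError`) rather than silently
producing a zero-feature row. The EZ line dropping to the RPE under SRF is
treated as a property of the *input* surfaces; the SRF mask, not surface
arithmetic, defines the fluid, because segmentation is upstream of this
pipeline.

## The 962-descriptor bank

The bank's published family cardinalities are 52 Haralick, 501 Laws, 383
Gabor and 26 CoLlAGe. The underlying parameter grids are not stated
anywhere, and neither 501 nor 383 factors cleanly over any natural grid, so
the bank is defined operationally by a versioned manifest
(`featureBankManifest()`), which enumerates canonical grids and truncates
each family to its published count. The manifest — not the grids — is the
single source of truth, and it ships as JSON with the package.

* **Haralick (52 = 13 × 4).** Thirteen classical gray-level co-occurrence
  statistics computed per voxel from a symmetric GLCM accumulated over a
  5³ sliding window (clipped to the compartment mask) across the 13 unique
  3D direction classes, times the four aggregation statistics folded into
  the feature name. Gray levels are quantized to 32 levels by min–max
  within the mask — a common radiomics default.
* **Laws (501 of 608).** All 27 three-point (`L3, E3, S3`) and 125
  five-point (`L5, E5, S5, R5, W5`) ordered kernel triplets, applied
  separably along (depth, A-scan, slice) with reflect padding; local energy
  is the 5³ windowed mean absolute response; 152 maps × 4 statistics = 608
  candidates, truncated by the manifest to the first 501 in canonical
  order.
* **Gabor (383 of 384).** A 2D complex Gabor bank (8 orientations × 4
  wavelengths {3, 4, 6, 8} voxels × 3 bandwidths {0.4, 0.6, 0.8}, with
  `sigma = bandwidth × wavelength`) applied slice-wise within the B-scan
  plane by FFT convolution; per-voxel magnitude; DC-corrected so constant
  regions respond 0. 96 maps × 4 statistics, truncated to 383.
* **CoLlAGe (26 = 13 × 2).** Central-difference gradients pooled into a 5³
  windowed structure tensor; the dominant eigenvector yields an in-plane
  angle in `[0, π)` and a through-plane angle in `[−π/2, π/2]`, quantized
  into 16 bins; the 13 Haralick statistics on the per-voxel angle
  co-occurrence matrix of each channel, aggregated by the median. 26 is
  not divisible by four, which forces the single-statistic reading for this
  family.

Aggregation uses median, variance (denominator *n*), skewness and
non-excess kurtosis over the masked voxels, folded into names such as
`IRF/Median-Laws_E3S3S3`. Degenerate cases are explicit conventions: a
single-voxel mask reports the median and missing higher moments;
zero-variance values report skewness and kurtosis 0; an empty compartment
yields 962 missing values, which are flagged, kept, and mean-imputed (as
post-normalization zeros) only inside the selection/classification stage.

Compartment tables fuse by column concatenation with compartment-prefixed
names: `F_f` = IRF + SRF (1924 columns), `F_RTC` = RTC1 + RTC2, and
`F_OCT` = all four (3848 columns).

## Statistical evaluation

Features are z-normalized to mean 0 and population sd 1 per column.
Normalization inside cross-validation is refit on fold-train rows only —
deliberately stricter than a cohort-wide normalization, to exclude leakage;
the cohort-wide variant remains available (`normalize = "cohort"`) for
fidelity runs. A canary test asserts the no-leakage property: a feature
that encodes the label only on held-out rows cannot raise CV performance.

Per fold, three rankings are computed. The Welch t-test and rank-sum tests
are vectorized; the rank-sum p-value uses the exact distribution when both
groups are small without ties and the tie-corrected normal approximation
otherwise. mRmR discretizes features into tertiles and greedily maximizes
relevance minus mean redundancy (the MID "difference" form, the most common
variant of the original formulation). The two-best rule intersects the
three top-15 sets and keeps the two lowest mean ranks (lexicographic name
tie-break — the source protocol names no criterion for "best" within the
intersection, and mean rank uses all three methods symmetrically); an
intersection smaller than two falls back to the union, flagged in the
selection audit.

Classifier hyperparameters are unstated upstream and fixed here as plain
defaults: LDA/QDA without shrinkage, random forest with 100 seeded trees,
linear-kernel SVM with probability calibration. Metrics are pooled over
all iteration × fold evaluations as mean ± sd, matching "0.78 ± 0.08"-style
reporting; a held-out 20% evaluation (selection and normalization refit on
the full training split) is reported alongside because the protocol's
phrasing is ambiguous about which of the two the headline numbers are.

For clustering, "top 10 features selected using PCA" is read as the ten
leading principal-component scores (the clustergram's axis labels
reduced-dimension features); component signs are fixed by the
largest-loading-positive convention. Ward linkage on Euclidean distances
matches the variance-minimizing objective of the K-means comparison. The
elbow is the maximum discrete second difference of the within-cluster sum
of squares over `k = 1..kMax`, flagged "weak" when the winning curvature is
less than twice the median of the rest.

The decision gate predicts rebounder when score ≥ threshold. The threshold
grid is the midpoints of sorted unique scores (plus a fixed 0.30–0.70 step
0.02 grid for table reporting). The target search returns the least
aggressive achieving threshold — smallest for a non-rebounder target,
largest for a rebounder target — so the other group's percentage is as
favourable as the target allows.

## The synthetic cohort generator

`generateCohort()` emulates the study conditions: 11 rebounders and 17
non-rebounders by default, at a desk-scale geometry of 64 slices × 96
depth × 64 A-scans (the full 128 × depth × 512 geometry is available by
setting `volumeShape`). Its model, chosen where the source gives none:

* **Geometry.** Three smooth low-frequency random surfaces with base
  depths at 22%, 55% and 78% of the axial range, ordering enforced, and a
  Gaussian foveal depression thinning the inner retina at the volume
  centre.
* **Speckle.** Multiplicative gamma speckle (shape 4, unit mean) over
  piecewise-constant band reflectivities (vitreous 25, inner retina 110,
  outer retina 180, choroid 60 on a nominal 8-bit scale — the intensity
  scale is a convention, not a measured fact). Gamma speckle on
  piecewise-constant reflectivity is the standard first-order OCT speckle
  approximation.
* **Fluid.** IRF pockets are discrete ellipsoids clipped to the ILM→EZ
  band; SRF pockets are lens-shaped caps under the EZ clipped to EZ→RPE;
  both are rendered hyporeflective (reflectivity × 0.35). Pocket centres
  are drawn from the central half of slices and A-scans because the
  emulated population is foveal-involving edema; this also guarantees the
  planted signal lies inside the mid-macular analysis window.
* **Class effect.** Rebounder eyes receive zero-mean spot-scale noise
  (white noise filtered by `S3 ⊗ S3 ⊗ S3`) inside the IRF mask. The
  effect is confined to IRF because the pipeline's central question is
  which compartment carries signal, and the planted ground truth must be
  recoverable by construction. `effectSize` is calibrated in units of the
  speckle-driven intensity sd inside fluid: at `effectSize = 1` the planted
  texture is as strong as the speckle background, at 0 the classes are
  exchangeable bit-for-bit (the noise field is drawn for every eye and
  scaled by zero, so RNG consumption is label-independent).

All randomness flows from one master seed through deterministically derived
per-eye seeds; regeneration is bit-for-bit reproducible.

What the generator does *not* emulate: vendor-specific intensity transfer
curves, shadowing and projection artifacts, motion, segmentation error, or
any longitudinal change. Passing tests on this cohort therefore show that
the pipeline recovers a known compartment-localized texture effect under
realistic speckle and geometry — they do not certify performance on
clinical scans.

## Problem sizes used by the shipped checks

The test suite and the acceptance script evaluate label recovery on 30
eyes per class at 16 × 64 × 48 voxels with 100 CV iterations — large
enough that the planted-effect AUC and the selection-concentration
fraction are stable, small enough to run routinely on one core. The
oracle-equivalence checks (exhaustive GLCM, dense convolution, concordant
pair counts) run on ≤ 8³ volumes and score vectors of length ≤ 8, where
brute force is exact and fast.

## Known limitations

* The Laws and Gabor grids behind the published 501/383 counts are not
  recoverable; the manifest records one defensible enumeration, versioned
  so that any future change is explicit.
* Haralick/CoLlAGe windows at compartment boundaries include partial
  windows (clipped to the mask) rather than discarding rim voxels; rim
  statistics are therefore estimated from fewer pairs.
* The 2D slice-wise Gabor family trades the (unspecified) 3D variant for
  an orientation-resolved in-plane bank; through-plane texture is covered
  by the Laws and CoLlAGe families.
* With 11 + 17 eyes at study scale, per-fold test sets are tiny; metric
  standard deviations across folds are accordingly large. This mirrors the
  emulated protocol rather than a defect of the implementation.
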