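---
title: "Radiomic tractometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic tractometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classic tractometry summarizes a diffusion-MRI parameter map (most
often the fractional anisotropy, FA) along a white-matter tract as a
short profile of per-segment means. Two ingredients limit what such
profiles can see. First, segment assignment is usually driven by a
single tract centerline: every streamline point (or voxel) is mapped to
its nearest of $n$ centerline points. In bundles that fan or split —
the cortical terminations of the corticospinal tract are the canonical
example — nearest-centerline assignment projects laterally distant
tissue onto a few central points and misorders segments along the
course. Second, a mean discards everything about the intensity
*distribution* and *spatial arrangement* inside a segment: two patient
groups that differ in tissue heterogeneity but not in mean FA are
invisible to a mean profile.

`tractomics` addresses both limitations:

1. **Voxel-space parcellation.** Streamlines are statically resampled
   to $n$ positions along their arc length; every sampled point is a
   training example whose class label is its position index
   $l \in [1 \ldots n]$. A multiclass support-vector classifier with an
   RBF kernel is fit to the 3-D point coordinates, and the trained
   decision function is evaluated at the center of every voxel of the
   tract envelope. The resulting label image is a partition of the
   tract into $n$ parcels whose borders are placed where the labeled
   point clouds actually separate — fanning and bending geometry is
   respected because the classifier lives in voxel space, not on a
   centerline.
2. **Per-parcel radiomics.** Each parcel is treated as a region of
   interest for a standardized radiomic feature set: 18 first-order
   statistics, 14 3-D shape descriptors, and 5 texture-matrix families
   (GLCM 22, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5 features), computed
   on the original image and on a bank of 11 filtered variants (3
   Laplacian-of-Gaussian scales and 8 stationary-wavelet sub-bands).
   Shape is geometric and therefore computed once, on the original
   parcel only. The budget per parcel is
   $105 + 11 \times 91 = 1106$ features.

Subject-level analysis feeds these features to a random-forest
classifier or regressor behind an automatic selection pipeline, with
repeated leave-one-out cross-validation and impurity-based importances
aggregated per parcel — turning a prediction into a along-tract
localization map.

## Parcellation details

**Number of parcels.** `estimate_num_parcels()` uses
$n_{\mathrm{auto}} = \mathrm{round}(n_{\mathrm{voxels}} / m)$, where
$n_{\mathrm{voxels}}$ is the mean number of unique voxels traversed per
streamline and $m$ (default 5) is the desired parcel thickness in
voxels along the course. The count is clamped to $\ge 1$. Traversal is
measured by walking each polyline at half the smallest voxel size and
collecting unique nearest voxels; the tests check this step against a
10-times-finer rasterization.

**Orientation.** Consistent point ordering across streamlines is
needed before position indices mean anything. With a start-region ROI,
a streamline is reversed when its last point is strictly closer than
its first to the nearest ROI voxel center (ties keep the input order —
a deterministic tie-break matters for reproducibility). Without a ROI,
orientation uses the minimum average direct-flip (MDF) distance to the
bundle centerline. Both operations are idempotent.

**Streamline reduction.** To keep training fast and to remove the bias
a dense bundle core would exert on the decision boundaries, bundles
are reduced to about 500 streamlines by a single-pass QuickBundles
scheme (running-mean centroids, MDF on 12-point resamplings). The MDF
threshold is found by bisection so the cluster count lands within
±10% of the target; when the discrete cluster-count landscape cannot
reach that band, seeded uniform subsampling to exactly the target
guarantees termination. The 12-point resampling for clustering is the
common QuickBundles practice; it is configurable.

**Training positions.** The $n$ training positions per streamline are
placed at the *centers* of $n$ equal arc-length bins,
$(k - \tfrac12)/n$, not at $k/(n-1)$ endpoints. With endpoint
placement, the Voronoi cell of the first and last position along the
course is only half as wide as the interior cells, so the end parcels
of a straight bundle would systematically be half-thickness;
cell-centered placement makes the ideal parcellation of a straight
tube exactly $n$ equal slabs, which is also what the automatic
$n_{\mathrm{voxels}}/m$ estimate assumes. The same cell-centered
placement is available for the baseline centerline
(`compute_centerline(..., positions = "centers")`) so the two methods
are compared on equal footing.

**Classifier.** A one-vs-one multiclass SVM with an RBF kernel and
default regularization ($C = 1$). Coordinates are centered and
isotropically scaled by the training cloud's RMS radius before
fitting, and the kernel bandwidth uses the
$1/(d \cdot \mathrm{Var})$ heuristic on the scaled coordinates; both
steps make the default bandwidth well-conditioned regardless of tract
size. A linear kernel is available via `kernel = "linear"`. Prediction
happens at voxel centers only — no sub-voxel soft assignment.

## Feature engine details

**Discretization.** Texture matrices and the first-order
entropy/uniformity need discrete gray levels. The default is a fixed
*bin count* of 32 equal-width bins spanning the parcel's own intensity
range (maximum maps into the top bin; constant parcels collapse to one
level). For FA-like inputs confined to $[0, 1]$ an absolute bin-width
default would collapse levels, which is why bin count is the robust
choice here; both the count and the mode are configurable. A
consequence worth knowing: range-relative binning makes all texture
features invariant to adding a constant to the image, but *not* to
rescaling contrast inside the parcel.

**Filter bank.** LoG scales are 1, 2 and 3 mm (sigma in physical
units, converted per axis to voxels, so anisotropic grids are handled);
the filter is scale-normalized ($\sigma^2 \nabla^2 G_\sigma$),
implemented as separable Gaussian smoothing followed by the discrete
Laplacian. The wavelet variant is a single-level undecimated separable
3-D Coiflet-1 transform with periodic boundary — all 8 sub-bands stay
on the original grid, and the test suite pins the transform to
reference values from an independent wavelet library. One LoG triplet
plus one wavelet level is exactly what produces an 11-image derived
bank.

**Texture geometry.** All five families use 26-connected 3-D
neighborhoods. GLCM and GLRLM are computed per direction over the 13
unique direction pairs and the *features* are averaged over directions
(not the matrices merged) — the averaging choice is configurable in
principle but fixed here as the default. GLSZM zones are 26-connected
components of equal gray level; GLDM uses dependence tolerance
$\alpha = 0$; NGTDM compares each voxel with the mean of its valid
neighbors. Matrices are trimmed to the gray levels actually present
before feature evaluation, so absent levels never produce 0/0
artifacts.

**Shape meshing.** Mesh volume and surface area come from a watertight
iso-surface at 0.5 on the binary parcel, built by marching tetrahedra
on a body-centered split: each 2×2×2 voxel-corner cell contributes 24
tetrahedra whose face- and body-center values are corner means. The
binary field is first smoothed with a symmetric face-neighbor kernel
(center weight 8/14) — symmetric smoothing leaves planar boundaries'
0.5-crossings exactly in place while rounding staircase corners, and
the chosen center weight keeps even an isolated voxel above threshold
so small disconnected fragments still mesh. On a digitized ball of
radius 8 voxels this yields sphericity ≈ 0.94 (a popular
marching-cubes implementation gives ≈ 0.92 on the same input).
Single-voxel parcels skip meshing and report voxel-based surrogates.
Axis lengths, elongation and flatness derive from the principal axes
of the voxel-center covariance ($4\sqrt{\lambda_i}$), and maximum
diameters from pairwise distances between voxel centers (with a
random-direction extreme-point reduction above 1500 voxels).

**Missing parcels.** A parcel index absent from the label image
produces a row of NA — flagged, never dropped. The selection pipeline
later discards columns containing NA rather than imputing.

## Prediction harness

Selection runs strictly inside each training fold and has three
deterministic stages in a fixed order: drop constant columns; greedily
drop one member of each pair with $|r| > 0.95$ (the earlier column is
kept — a stable tie-break); rank the rest by a univariate F statistic
(one-way ANOVA for classification, simple-regression F for continuous
outcomes) and keep the top 500. Because the stages involve no
randomness, fold-wise selections are computed once and shared across
the differently seeded repetitions.

Classification is a 500-tree random forest with no tuning, evaluated
by ten differently seeded leave-one-out cross-validations; AUROC is
computed per seed over the pooled held-out class probabilities
(one-vs-rest macro average beyond two classes) and reported as
mean ± sd over seeds. Regression uses a fixed 70/30 split stratified
by outcome quartile (the split fraction is a package default; any
fixed split can be supplied), reporting MAE and Pearson r with an
uncorrected two-sided t-test; constant predictions are flagged and
reported as $r = 0$, $p = 1$ while MAE stays valid. Per-model
impurity importances are normalized to sum to 1, averaged over folds
and seeds, and summed per parcel or per feature family — so parcel
importances again sum to 1 when the grouping covers all features.
Paired method comparisons use the two-sided Wilcoxon signed-rank test
(exact null for $n \le 25$ non-zero differences) with a Bonferroni
cap.

One property of pooled leave-one-out evaluation is worth keeping in
mind when reading AUROC values near chance: holding out a subject
leaves its class underrepresented in the training fold, which biases
the held-out probability *against* the true class. Under permuted
labels the pooled-LOO AUROC therefore sits at or below 0.5 (clearly
below it for small cohorts), not at 0.5. This pessimism is inherent to
the design, affects both methods being compared equally, and cannot
manufacture spurious above-chance performance — which is why the test
suite checks the null from above (no leakage) rather than asserting a
symmetric chance band.

Feature subsets (e.g. "first-order only", "wavelet images only") are
applied *before* selection, mirroring the order in which the analysis
stages are described.

## What the phantoms emulate — and what they do not

`make_bundle()` generates tube, fan and arc bundles: polylines sharing
a trunk, with per-streamline cross-section offsets, optional linear
divergence after 60% of the course (fan) and per-point Gaussian
jitter. Ground-truth parcels are equal-arc-length bins of each
streamline rasterized by majority vote (ties toward the lower label);
envelope voxels reached only by dilation inherit the nearest label.
`make_cohort()` builds two balanced groups of subjects, each with an
independently jittered bundle and an FA-like image: smoothed white
noise (4 mm kernel) rescaled to $[0.3, 0.7]$ plus white noise of sd
0.03, clipped to $[0, 1]$ — a plausible FA dynamic range. Group B
carries either a mean shift ($+\delta$, default 0.1) or a texture
effect (noise sd multiplied by $\rho$, default 2, re-centered so
parcel means match group A) inside one chosen parcel.

These phantoms exercise geometry (fanning vs straight), the full
feature stack, and effect recovery end to end, with effect sizes a
scientist would call strong-but-plausible for group studies. They do
**not** emulate crossing fibers, partial-volume effects at tract
borders, registration error, scanner site effects, or spatially
correlated physiological noise; passing the synthetic suite therefore
demonstrates correctness of the machinery, not expected effect sizes
on real cohorts. The headline synthetic result — that per-parcel
radiomics detects a mean-preserving texture effect (AUROC ≥ 0.8 at 25
subjects/group) where 100-point mean profiles stay near chance — is by
construction: mean profiles are sufficient statistics only for mean
effects.

## Numerical choices and degenerate inputs

* World frame is RAS millimetres everywhere; voxel indices are 0-based
  with centers at integer indices, and nearest-voxel membership rounds
  half *down* (ties to the lower index). TRK's corner-based voxel-mm
  convention is normalized on load; TCK stores world mm directly but
  carries no grid, so a reference image may be attached.
* Problem sizes in the shipped tests: phantom grids of 24×24×48 to
  24×24×90 voxels at 1 mm, 200 streamlines per bundle, cohorts of
  2×25 subjects, 10 CV seeds — sizes chosen so the whole suite runs on
  a laptop in minutes while still exercising every code path at the
  study's structural scale (e.g. the 17-parcel, 18,802-feature tract).
* The reduction band ±10% around the 500-streamline target
  operationalizes "about 500"; bisection runs at most 40 iterations.
* `parcelwise_dice()` defines 1 for two empty parcels and 0 when
  exactly one is empty.
* Wilcoxon p-values switch from the exact null to the normal
  approximation above 25 non-zero differences.
* Tract envelopes may come from a segmentation mask or from streamline
  visitation (the phantom generator uses visited-voxels dilated by
  one); when a mask is available it takes precedence, since
  segmentation-based envelopes are usually the more conservative
  region definition.

## Known limitations

* Parcel borders are purely geometric; no anatomical priors constrain
  them.
* One tract is parcellated at a time; joint multi-tract models are out
  of scope.
* The feature registry mirrors the *default-enabled* sets of the
  standard radiomics tooling; deprecated or redundant variants (e.g.
  GLCM sum-average) are intentionally absent.
* `read_tractogram()` supports TRK and TCK; TRK scalars/properties are
  skipped on read and not written.

## A minimal session

```{r, eval = FALSE}
library(tractomics)

bundle <- make_bundle(phantom_spec("fan", fan_half_angle_deg = 40))
parc <- parcellate_tract(bundle$tractogram, bundle$envelope,
                         start_roi = bundle$start_roi, n = "auto")
fa <- make_subject_image(bundle, "A", cohort_spec(), subject_seed = 1)
feats <- extract_features_per_parcel(fa, parc$labels)
dim(feats)          # n parcels x (3 id columns + 1106 features)
```
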