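# tractomics

Radiomic tractometry for diffusion-MRI: voxel-space parcellation of
white-matter tracts and per-parcel radiomic feature extraction, with a
random-forest prediction harness that maps group differences back onto
tract parcels.

## Who this is for

Researchers doing along-tract analysis of scalar parameter maps (FA,
MD, or any co-registered contrast) who want more than the classic
100-point mean profile: a tract parcellation that survives fanning and
bending geometry, and a feature set rich enough to detect group
differences that preserve the mean (heterogeneity, texture, shape).

## The method in brief

**Parcellation.** A tract is a bundle of streamlines; each streamline
is resampled to *n* positions along its arc length and every sampled
point becomes a training example labeled by its position index
*l* ∈ [1…*n*]. A multiclass RBF support-vector machine fit to the 3-D
point coordinates then labels every voxel of the tract envelope — the
parcel borders are the SVM decision boundaries in voxel space, so
fanning regions are segmented where the labeled point clouds actually
separate instead of being projected onto a centerline. The parcel
count can be set automatically as

  n_auto = round(n_voxels / m),

where n_voxels is the mean number of voxels traversed per streamline
and *m* (default 5) is the desired parcel thickness in voxels. Bundles
are first reduced to about 500 streamlines by QuickBundles clustering
(MDF distance, running-mean centroids) so that dense bundle cores do
not bias the decision boundaries.

**Features.** Each parcel yields 105 features on the original image
(14 shape + 18 first-order + 73 texture across GLCM/GLRLM/GLSZM/GLDM/
NGTDM) and 91 on each of 11 filtered image variants (3
Laplacian-of-Gaussian scales and 8 stationary Coiflet-1 wavelet
sub-bands) — 1106 features per parcel.

**Prediction.** Features feed a 500-tree random forest behind an
automatic selection pipeline (drop constants → prune |r| > 0.95 pairs
→ univariate top-500), evaluated by ten differently seeded
leave-one-out cross-validations. Impurity importances are aggregated
per parcel, localizing the signal along the tract. The classic
100-point mean profile is included as the baseline.

See `vignettes/radiomic-tractometry.Rmd` for the full methods account.

## Worked example

Everything below runs without any imaging data, using the built-in
phantom generator.

```r
library(tractomics)

# a fanning bundle with a known ground-truth parcellation
bundle <- make_bundle(phantom_spec("fan", fan_half_angle_deg = 40,
                                   grid_shape = c(64L, 24L, 48L)))
parc <- parcellate_tract(bundle$tractogram, bundle$envelope,
                         start_roi = bundle$start_roi, n = "auto", m = 5)
parc$n
#> [1] 11

# an FA-like image and its per-parcel features
fa <- make_subject_image(bundle, "A", cohort_spec(), subject_seed = 1)
feats <- extract_features_per_parcel(fa, parc$labels)
dim(feats)
#> [1]   11 1109
feats[1, c("original_firstorder_Mean", "original_shape_VoxelVolume",
           "original_glcm_Contrast")]
#>   original_firstorder_Mean original_shape_VoxelVolume original_glcm_Contrast
#> 1                 0.454829                        234               64.91654
```

The first parcel here averages FA ≈ 0.45 over its 234 mm³, and its
gray-level co-occurrence contrast (64.9 at 32 bins) measures how
sharply neighboring intensities differ — none of which a mean profile
records. On a two-group cohort with a mean-preserving texture effect
injected into parcel 3:

```r
subs <- make_cohort(cohort_spec(effect = "texture", seed = 7),
                    phantom_spec("tube", seed = 1))
fm <- cohort_feature_matrix(subs, n_parcels = 5)
rep_rt <- cross_validate_classifier(fm$X, fm$y, n_seeds = 10)
rep_rt$mean_auroc
#> [1] 1

pm <- cohort_profile_matrix(subs)
cross_validate_classifier(pm$X, pm$y, n_seeds = 10)$mean_auroc
#> [1] 0.56784

round(aggregate_importance(rep_rt, fm$maps$parcel)$parcel, 3)
#>   p01   p02   p03   p04   p05
#> 0.005 0.041 0.851 0.099 0.003
```

Radiomic features separate the groups perfectly (AUROC 1.0) while the
mean-profile baseline stays near chance (0.57), and the parcel
importance map points at parcel 3 — the parcel that actually carries
the effect.

A command-line wrapper for shell pipelines lives at
`inst/cli/tractomics` (subcommands `parcellate`, `features`,
`profile`, `predict`, `simulate`; TRK/TCK and NIfTI in, NIfTI/CSV/JSON
out).

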