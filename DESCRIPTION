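Package: tractomics
Title: Radiomic Tractometry of White-Matter Tracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Along-tract analysis of diffusion-MRI parameter maps beyond
    per-parcel means. Parcellates white-matter tracts directly in voxel
    space with a multiclass support-vector classifier trained on streamline
    point coordinates, extracts standardized radiomic features (first-order,
    3-D shape, and five gray-level texture-matrix families on a bank of
    Laplacian-of-Gaussian and wavelet filtered image variants) per parcel,
    and evaluates subject-level prediction with random forests, repeated
    leave-one-out cross-validation, and parcel-importance mapping. Includes
    the classic centerline tract-profile baseline, streamline utilities
    (arc-length resampling, minimum average direct-flip distance,
    QuickBundles-style reduction), TRK/TCK and NIfTI input/output, and a
    synthetic phantom generator for validation without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    e1071,
    ranger,
    pROC,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
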