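# Per-parcel feature extraction: applies the filter bank, discretizes
# per parcel and image variant, and evaluates all feature families
# under a fixed registry of column names. The default configuration
# yields 105 features on the original image (14 shape + 91 intensity/
# texture) and 91 on each of the 11 derived images: 1106 per parcel.

#' Feature-extraction configuration
#'
#' @param families Feature families to compute.
#' @param sigmas_mm Laplacian-of-Gaussian scales in mm.
#' @param wavelet Include the 8 wavelet sub-bands.
#' @param n_bins Discretization bin count (fixed-bin-count mode).
#' @param subset_name One of the 12 analysis subsets: `"all"`, a single
#'   family name (that family on all image variants), `"original"`,
#'   `"log"`, `"wavelet"` (all families on those variants only), or
#'   `"firstorder-original"`.
#' @return A `feature_config` list.
#' @export
feature_config <- function(families = c("firstorder", "shape", "glcm", "glrlm",
                                        "glszm", "gldm", "ngtdm"),
                           sigmas_mm = c(1, 2, 3), wavelet = TRUE,
                           n_bins = 32L, subset_name = "all") {
  families <- match.arg(families, several.ok = TRUE,
                        choices = c("firstorder", "shape", "glcm", "glrlm",
                                    "glszm", "gldm", "ngtdm"))
  stopifnot(n_bins >= 2L)
  structure(list(families = families, sigmas_mm = sigmas_mm,
                 wavelet = wavelet, n_bins = as.integer(n_bins),
                 subset_name = subset_name),
            class = "feature_config")
}

.FAMILY_SIZES <- c(firstorder = 18L, shape = 14L, glcm = 22L, glrlm = 16L,
                   glszm = 16L, gldm = 14L, ngtdm = 5L)

.family_feature_names <- function(family) {
  switch(family,
         firstorder = names(compute_first_order(c(0, 1))),
         shape = names(compute_shape(array(1, c(1, 1, 1)))),
         glcm = names(.glcm_one(matrix(1, 1, 1), 1)),
         glrlm = names(.rl_features(matrix(1, 1, 1), 1, 1, "glrlm",
                                    .GLRLM_NAMES)),
         glszm = names(.rl_features(matrix(1, 1, 1), 1, 1, "glszm",
                                    .GLSZM_NAMES)),
         gldm = names(.gldm_features(matrix(1, 1, 27), 1, 1)),
         ngtdm = names(.ngtdm_features(matrix(c(1, 0), 1, 2), 1)))
}

.GLRLM_NAMES <- c("ShortRunEmphasis", "LongRunEmphasis",
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                  "RunPercentage", "GrayLevelVariance", "RunVariance",
                  "RunEntropy", "LowGrayLevelRunEmphasis",
                  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                  "LongRunHighGrayLevelEmphasis")
.GLSZM_NAMES <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                  "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                  "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                  "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                  "SmallAreaHighGrayLevelEmphasis",
                  "LargeAreaLowGrayLevelEmphasis",
                  "LargeAreaHighGrayLevelEmphasis")

#' Registry of feature column names for a configuration
#'
#' Column names follow `filter_family_feature` (e.g.
#' `original_glcm_Contrast`, `wavelet.LLH_firstorder_Mean`). Shape is
#' computed on the original geometry only. With defaults this yields
#' exactly 1106 names: 105 for the original image and 91 per derived
#' image.
#'
#' @param config A [feature_config()].
#' @return Character vector of column names, stable across runs.
#' @export
feature_registry <- function(config = feature_config()) {
  imgs <- "original"
  for (s in config$sigmas_mm)
    imgs <- c(imgs, paste0("log.sigma.", gsub("\\.", "-", format(s)), "mm"))
  if (config$wavelet) {
    combos <- expand.grid(c("L", "H"), c("L", "H"), c("L", "H"),
                          stringsAsFactors = FALSE)
    imgs <- c(imgs, paste0("wavelet.",
                           sort(do.call(paste0, combos))))
  }
  cols <- character(0)
  for (im in imgs) {
    fams <- setdiff(config$families, "shape")
    if (im == "original" && "shape" %in% config$families)
      cols <- c(cols, paste0(im, "_", .family_feature_names("shape")))
    for (fam in fams)
      cols <- c(cols, paste0(im, "_", .family_feature_names(fam)))
  }
  .apply_subset(cols, config$subset_name)
}

.apply_subset <- function(cols, subset_name) {
  if (subset_name == "all") return(cols)
  img <- sub("_.*$", "", cols)
  fam <- sub("^[^_]+_([a-z]+)_.*$", "\\1", cols)
  keep <- switch(subset_name,
                 firstorder = fam == "firstorder",
                 shape = fam == "shape",
                 glcm = fam == "glcm",
                 glrlm = fam == "glrlm",
                 glszm = fam == "glszm",
                 gldm = fam == "gldm",
                 ngtdm = fam == "ngtdm",
                 original = img == "original",
                 log = startsWith(img, "log."),
                 wavelet = startsWith(img, "wavelet."),
                 `firstorder-original` = fam == "firstorder" & img == "original",
                 stop("unknown subset: ", subset_name))
  cols[keep]
}

#' Extract radiomic features for every parcel of a tract
#'
#' Applies the filter bank to the image and computes, per parcel, shape
#' features on the original geometry plus first-order and texture
#' features on every image variant, discretizing intensities per parcel
#' and variant. Parcels absent from the label image yield rows of NA
#' (flagged, never silently dropped).
#'
#' @param img `scalar_image` (e.g. an FA map).
#' @param parcels `label_image` from [parcellate_voxels()].
#' @param config A [feature_config()].
#' @param subject,tract Identifiers recorded in the output.
#' @return A data.frame with columns `subject`, `tract`, `parcel`, then
#'   one column per registry feature.
#' @export
extract_features_per_parcel <- function(img, parcels, config = feature_config(),
                                        subject = "subj", tract = "tract") {
  if (!identical(dim(img$data), dim(parcels$data))) stop("grids differ")
  n <- parcels$n_parcels
  if (n < 1L) stop("no parcels")
  cols <- feature_registry(config)
  vox_vol <- prod(img$voxel_size)
  rows <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  bank <- apply_filter_bank(
    img,
    sigmas_mm = if (any(startsWith(cols, "log."))) config$sigmas_mm
                else numeric(0),
    wavelet = any(startsWith(cols, "wavelet.")))
  img_names <- unique(sub("_.*$", "", cols))
  for (k in seq_len(n)) {
    sel <- parcels$data == k
    if (!any(sel)) next                      # NA row, flagged
    bb <- .bbox(sel)
    msk <- sel[bb$x, bb$y, bb$z, drop = FALSE]
    for (im in img_names) {
      vals_img <- bank[[im]]$data[bb$x, bb$y, bb$z, drop = FALSE]
      vals <- vals_img[msk]
      pre <- paste0(im, "_")
      if (im == "original" && any(startsWith(cols, "original_shape_"))) {
        sh <- compute_shape(msk, img$voxel_size)
        rows[k, paste0(pre, names(sh))] <- sh
      }
      fams <- setdiff(unique(sub("^[^_]+_([a-z]+)_.*$", "\\1",
                                 cols[startsWith(cols, pre)])), "shape")
      if ("firstorder" %in% fams) {
        fo <- compute_first_order(vals, vox_vol, config$n_bins)
        rows[k, paste0(pre, names(fo))] <- fo
      }
      tex <- intersect(fams, c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
      if (length(tex)) {
        disc <- array(0L, dim(msk))
        disc[msk] <- discretize_intensities(vals, config$n_bins)
        for (fam in tex) {
          tf <- compute_texture_family(fam, disc)
          rows[k, paste0(pre, names(tf))] <- tf
        }
      }
    }
  }
  data.frame(subject = subject, tract = tract, parcel = seq_len(n), rows,
             check.names = FALSE, row.names = NULL)
}

.bbox <- function(sel) {
  idx <- which(sel, arr.ind = TRUE)
  list(x = min(idx[, 1]):max(idx[, 1]),
       y = min(idx[, 2]):max(idx[, 2]),
       z = min(idx[, 3]):max(idx[, 3]))
}

#' Write/read a feature table
#'
#' Long format uses the `subject,tract,parcel,feature,value` schema;
#' wide format keeps one column per feature.
#'
#' @param x Feature data.frame from [extract_features_per_parcel()].
#' @param path Output CSV path.
#' @param format `"wide"` (default) or `"long"`.
#' @export
write_feature_table <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "long") {
    idcols <- c("subject", "tract", "parcel")
    feats <- setdiff(names(x), idcols)
    x <- data.frame(x[rep(seq_len(nrow(x)), times = length(feats)), idcols],
                    feature = rep(feats, each = nrow(x)),
                    value = unlist(x[feats], use.names = FALSE),
                    row.names = NULL)
  }
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

# ---- classic tract profile -------------------------------------------------

#' Classic centerline tract profile
#'
#' The along-tract baseline: the image is sampled (trilinear) at every
#' streamline point, each sample is assigned to the nearest of
#' `n_profile` centerline points, and per-bin means are returned. Bins
#' visited by no point yield NA.
#'
#' @param img `scalar_image` to profile.
#' @param t Orientation-aligned `tractogram`.
#' @param n_profile Number of profile points (default 100).
#' @param centerline Optional fixed centerline (defaults to the
#'   pointwise-mean centerline of `t` at `n_profile` points).
#' @return Numeric vector of length `n_profile`.
#' @export
classic_tract_profile <- function(img, t, n_profile = 100L, centerline = NULL) {
  if (length(t$streamlines) == 0L) stop("tractogram is empty")
  if (is.null(centerline)) centerline <- compute_centerline(t, n_profile)
  cpts <- .as_points(centerline)
  if (nrow(cpts) != n_profile) stop("centerline must have n_profile points")
  pts <- do.call(rbind, lapply(t$streamlines, unclass))
  vals <- sample_trilinear(img, pts)
  d2 <- outer(rowSums(pts^2), rowSums(cpts^2), "+") - 2 * pts %*% t(cpts)
  bin <- max.col(-d2, ties.method = "first")
  ok <- !is.na(vals)
  prof <- rep(NA_real_, n_profile)
  agg <- tapply(vals[ok], bin[ok], mean)
  prof[as.integer(names(agg))] <- agg
  prof
}

#' Trilinear image sampling at world coordinates
#'
#' @param img `scalar_image`.
#' @param points n x 3 world coordinates (mm).
#' @return Sampled intensities; NA outside the grid.
#' @export
sample_trilinear <- function(img, points) {
  idx <- world_to_index(img, .as_points(points))
  d <- dim(img$data)
  i0 <- floor(idx)
  f <- idx - i0
  out <- numeric(nrow(idx))
  valid <- i0[, 1] >= -1 & i0[, 1] <= d[1] - 1 &
    i0[, 2] >= -1 & i0[, 2] <= d[2] - 1 &
    i0[, 3] >= -1 & i0[, 3] <= d[3] - 1
  out[!valid] <- NA_real_
  get_at <- function(ii, jj, kk) {
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    v <- numeric(length(ii))
    v[ok] <- img$data[cbind(ii[ok] + 1L, jj[ok] + 1L, kk[ok] + 1L)]
    v
  }
  vi <- which(valid)
  if (length(vi)) {
    acc <- numeric(length(vi))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[vi, 1] else 1 - f[vi, 1]) *
        (if (dy) f[vi, 2] else 1 - f[vi, 2]) *
        (if (dz) f[vi, 3] else 1 - f[vi, 3])
      acc <- acc + w * get_at(i0[vi, 1] + dx, i0[vi, 2] + dy, i0[vi, 3] + dz)
    }
    out[vi] <- acc
  }
  out
}
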