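# Convenience wrappers tying the modules together: one-call tract
# parcellation, per-subject feature vectors, and cohort-level feature /
# profile matrices ready for the prediction harness.

#' Parcellate a tract end to end
#'
#' Orients the streamlines (start-region ROI if given, else MDF to the
#' bundle centerline), determines the parcel count (the n_voxels / m
#' automatic estimate when `n = "auto"`), fits the voxel-space
#' classifier, and
#' labels the tract envelope.
#'
#' @param t A `tractogram`.
#' @param mask `binary_mask` tract envelope to label.
#' @param start_roi Optional `binary_mask` start region for orientation.
#' @param n Parcel count, or `"auto"` for the automatic estimate.
#' @param m Desired parcel thickness in voxels (used when `n = "auto"`).
#' @param seed Seed for reduction/classifier determinism.
#' @param baseline If `"centerline"`, use nearest-centerline-point
#'   assignment instead of the classifier.
#' @return List: `labels` (a `label_image`), `n`, `model` (NULL for the
#'   baseline), `oriented` (the oriented tractogram).
#' @export
parcellate_tract <- function(t, mask, start_roi = NULL, n = "auto", m = 5L,
                             seed = 1L, baseline = c("none", "centerline")) {
  baseline <- match.arg(baseline)
  t <- if (!is.null(start_roi)) orient_by_start_roi(t, start_roi)
       else orient_by_centerline(t, compute_centerline(t, 12L))
  if (identical(n, "auto")) n <- estimate_num_parcels(t, mask, m = m)
  n <- as.integer(n)
  if (baseline == "centerline") {
    cl <- compute_centerline(t, n, positions = "centers")
    return(list(labels = centerline_parcellation(cl, mask), n = n,
                model = NULL, oriented = t))
  }
  model <- fit_parcellation_model(t, n, seed = seed)
  list(labels = parcellate_voxels(model, mask), n = n, model = model,
       oriented = t)
}

#' Flatten a per-parcel feature table into one named subject vector
#'
#' Column names are `p<k>_<filter>_<family>_<feature>`; the parcel and
#' family of every entry remain recoverable via [feature_group_maps()].
#'
#' @param ft Data.frame from [extract_features_per_parcel()].
#' @return Named numeric vector of length n_parcels x n_features.
#' @export
flatten_feature_table <- function(ft) {
  v <- as.matrix(ft[, setdiff(names(ft), c("subject", "tract", "parcel")),
                    drop = FALSE])
  out <- as.vector(t(v))
  names(out) <- paste0("p", sprintf("%02d", rep(ft$parcel, each = ncol(v))),
                       "_", rep(colnames(v), times = nrow(v)))
  out
}

#' Parcel and family lookup for flattened feature names
#'
#' @param feature_names Names produced by [flatten_feature_table()].
#' @return List of two named vectors: `parcel` (e.g. "p03") and
#'   `family` (e.g. "glcm").
#' @export
feature_group_maps <- function(feature_names) {
  parcel <- sub("^(p[0-9]+)_.*$", "\\1", feature_names)
  family <- sub("^p[0-9]+_[^_]+_([a-z]+)_.*$", "\\1", feature_names)
  list(parcel = setNames(parcel, feature_names),
       family = setNames(family, feature_names))
}

#' Cohort feature matrix (subjects x flattened parcel features)
#'
#' Runs the full parcellation + extraction pipeline for every subject
#' of a phantom cohort (see [make_cohort()]).
#'
#' @param subjects List of subjects from [make_cohort()].
#' @param n_parcels Parcel count used for every subject.
#' @param config A [feature_config()].
#' @param seed Parcellation seed.
#' @return List: `X` (matrix), `y` (group labels), `maps`
#'   (from [feature_group_maps()]).
#' @export
cohort_feature_matrix <- function(subjects, n_parcels, config = feature_config(),
                                  seed = 1L) {
  rows <- lapply(subjects, function(s) {
    pc <- parcellate_tract(s$tractogram, s$envelope, start_roi = s$start_roi,
                           n = n_parcels, seed = seed)
    flatten_feature_table(
      extract_features_per_parcel(s$image, pc$labels, config,
                                  subject = s$id))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(subjects, `[[`, "", "id")
  list(X = X, y = vapply(subjects, `[[`, "", "group"),
       maps = feature_group_maps(colnames(X)))
}

#' Cohort matrix of classic centerline tract profiles
#'
#' @param subjects List of subjects from [make_cohort()].
#' @param n_profile Profile length (default 100).
#' @return List: `X` (subjects x n_profile matrix of per-bin means,
#'   empty bins imputed with the row mean), `y` (group labels).
#' @export
cohort_profile_matrix <- function(subjects, n_profile = 100L) {
  rows <- lapply(subjects, function(s) {
    tg <- orient_by_start_roi(s$tractogram, s$start_roi)
    classic_tract_profile(s$image, tg, n_profile)
  })
  X <- do.call(rbind, rows)
  # random forests cannot digest NA: impute rare empty bins per subject
  for (i in seq_len(nrow(X))) {
    nas <- is.na(X[i, ])
    if (any(nas)) X[i, nas] <- mean(X[i, ], na.rm = TRUE)
  }
  colnames(X) <- sprintf("profile%03d", seq_len(n_profile))
  rownames(X) <- vapply(subjects, `[[`, "", "id")
  list(X = X, y = vapply(subjects, `[[`, "", "group"))
}
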