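# Streamline geometry: arc-length resampling, MDF distance, orientation
# alignment, centerlines, QuickBundles-style reduction, and traversed-
# voxel counting.

#' Resample a streamline to n equidistant points
#'
#' Points are placed at equal arc-length spacing along the input
#' polyline; the first and last points are preserved exactly.
#'
#' @param s A `streamline` (or n x 3 matrix).
#' @param n Number of output points (>= 2).
#' @return A `streamline` with n points.
#' @export
resample_streamline <- function(s, n) {
  if (n < 2L) stop("n must be >= 2")
  s <- .as_points(s)
  out <- .arc_resample(s, seq(0, 1, length.out = n))
  out[1, ] <- s[1, ]
  out[n, ] <- s[nrow(s), ]
  structure(out, class = "streamline")
}

# Points at the given arc-length fractions (0..1) along the polyline.
# cum is strictly increasing because consecutive points are distinct.
.arc_resample <- function(s, fracs) {
  seg <- sqrt(rowSums(diff(s)^2))
  cum <- c(0, cumsum(seg))
  target <- fracs * cum[length(cum)]
  cbind(approx(cum, s[, 1], xout = target)$y,
        approx(cum, s[, 2], xout = target)$y,
        approx(cum, s[, 3], xout = target)$y)
}

#' Minimum average direct-flip (MDF) distance between two streamlines
#'
#' Both streamlines are resampled to `n` points; the distance is the
#' smaller of the mean pointwise Euclidean distance computed directly
#' and with the second streamline reversed.
#'
#' @param a,b Streamlines (n x 3 matrices).
#' @param n Resampling count used for the comparison (default 12).
#' @return List with elements `distance` (mm) and `flipped` (logical;
#'   TRUE if the reversed orientation attained the minimum).
#' @export
mdf_distance <- function(a, b, n = 12L) {
  pa <- unclass(resample_streamline(a, n))
  pb <- unclass(resample_streamline(b, n))
  d_direct <- mean(sqrt(rowSums((pa - pb)^2)))
  d_flip <- mean(sqrt(rowSums((pa - pb[n:1, , drop = FALSE])^2)))
  if (d_flip < d_direct) list(distance = d_flip, flipped = TRUE)
  else list(distance = d_direct, flipped = FALSE)
}

#' Align streamline orientations
#'
#' `orient_by_start_roi()` reverses a streamline iff its last point is
#' strictly closer than its first point to the nearest nonzero voxel
#' center of the start-region ROI (ties keep the input order).
#' `orient_by_centerline()` reverses a streamline iff the flipped
#' orientation attains its MDF minimum to the given centerline. Both are
#' idempotent.
#'
#' @param t A `tractogram`.
#' @param roi A `binary_mask` delineating the start region.
#' @return The tractogram with consistently oriented streamlines.
#' @export
orient_by_start_roi <- function(t, roi) {
  centers <- voxel_centers(roi)        # errors on empty ROI
  t$streamlines <- lapply(t$streamlines, function(s) {
    d_first <- min(.pt_dists(s[1, ], centers))
    d_last <- min(.pt_dists(s[nrow(s), ], centers))
    if (d_last < d_first) .reverse_streamline(s) else s
  })
  t
}

#' @rdname orient_by_start_roi
#' @param c A centerline (n x 3 matrix, >= 2 points).
#' @param n Resampling count for the MDF comparison.
#' @export
orient_by_centerline <- function(t, c, n = 12L) {
  cpts <- .as_points(c)
  if (nrow(cpts) < 2L) stop("centerline needs at least 2 points")
  t$streamlines <- lapply(t$streamlines, function(s) {
    if (mdf_distance(s, cpts, n)$flipped) .reverse_streamline(s) else s
  })
  t
}

.reverse_streamline <- function(s) {
  structure(unclass(s)[nrow(s):1, , drop = FALSE], class = "streamline")
}

.pt_dists <- function(p, pts) sqrt(colSums((t(pts) - p)^2))

#' Pointwise-mean centerline of an orientation-aligned tractogram
#'
#' Point k of the centerline is the mean of point k over all streamlines
#' resampled to n points. Requires consistent orientation (see
#' [orient_by_start_roi()]).
#'
#' @param t A `tractogram` with orientation-aligned streamlines.
#' @param n Number of centerline points.
#' @param positions `"endpoints"` places the n points at arc fractions
#'   0..1 inclusive; `"centers"` places them at the centers of n equal
#'   arc-length bins (useful when the centerline defines a parcellation
#'   whose Voronoi cells should be equal slabs).
#' @return A `streamline` of n points.
#' @export
compute_centerline <- function(t, n = 100L,
                               positions = c("endpoints", "centers")) {
  positions <- match.arg(positions)
  if (length(t$streamlines) == 0L) stop("tractogram is empty")
  fracs <- if (positions == "centers") (seq_len(n) - 0.5) / n
           else seq(0, 1, length.out = n)
  acc <- matrix(0, n, 3)
  for (s in t$streamlines) acc <- acc + .arc_resample(.as_points(s), fracs)
  structure(acc / length(t$streamlines), class = "streamline")
}

#' Reduce a tractogram by QuickBundles-style clustering
#'
#' Streamlines are clustered with a single-pass scheme: each streamline
#' (resampled to `n_points`) is merged into the nearest cluster by MDF
#' to the running-mean centroid if within the distance threshold, else
#' starts a new cluster. The threshold is found by bisection so the
#' cluster count lands within +/-10% of `target`; if the band cannot be
#' reached, seeded uniform subsampling to exactly `target` is used.
#' Cluster centroids are returned as the reduced streamlines.
#'
#' @param t A `tractogram`.
#' @param target Desired number of output streamlines (>= 1).
#' @param seed Integer seed (used only by the subsampling fallback).
#' @param n_points Resampling count for clustering distances.
#' @return A `tractogram` with at most ~1.1 * target streamlines.
#' @export
reduce_streamlines <- function(t, target = 500L, seed = 1L, n_points = 12L) {
  if (target < 1L) stop("target must be >= 1")
  n_in <- length(t$streamlines)
  if (n_in <= target) return(t)
  pts <- array(0, c(n_points, 3L, n_in))
  for (i in seq_len(n_in))
    pts[, , i] <- unclass(resample_streamline(t$streamlines[[i]], n_points))
  lo <- 0; hi <- .qb_max_threshold(pts)
  band <- c(ceiling(0.9 * target), floor(1.1 * target))
  best <- NULL
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    cl <- quickbundles_cpp(pts, mid)
    k <- max(cl$assignment)
    if (k >= band[1] && k <= band[2]) { best <- cl; break }
    if (k > band[2]) lo <- mid else hi <- mid
  }
  if (is.null(best)) {
    set.seed(seed)
    keep <- sort(sample.int(n_in, target))
    t$streamlines <- t$streamlines[keep]
    return(t)
  }
  k <- max(best$assignment)
  reps <- lapply(seq_len(k), function(j) {
    structure(matrix(best$centroids[, , j], n_points, 3), class = "streamline")
  })
  t$streamlines <- reps
  t
}

# Upper bisection bound: diameter of the bundle's bounding box.
.qb_max_threshold <- function(pts) {
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  sqrt(sum((hi - lo)^2)) + 1
}

#' Number of unique voxels traversed by a streamline
#'
#' The polyline is walked at a step of half the minimum voxel size and
#' each visited position is assigned to its nearest voxel; the count of
#' unique in-grid voxel indices is returned (0 if the streamline lies
#' entirely outside the grid). Invariant to point-order reversal.
#'
#' @param s A `streamline`.
#' @param grid A `scalar_image` (or anything with shape + affine).
#' @param step Walking step in mm; default half the minimum voxel size.
#' @return Integer voxel count.
#' @export
count_traversed_voxels <- function(s, grid, step = NULL) {
  shape <- if (inherits(grid, "ref_grid")) grid$shape else dim(grid$data)
  vs <- if (inherits(grid, "ref_grid")) grid$voxel_size else grid$voxel_size
  if (is.null(step)) step <- min(vs) / 2
  pts <- .densify(.as_points(s), step)
  idx <- .round_index(world_to_index(.as_affine(grid), pts))
  inside <- idx[, 1] >= 0 & idx[, 1] < shape[1] &
    idx[, 2] >= 0 & idx[, 2] < shape[2] &
    idx[, 3] >= 0 & idx[, 3] < shape[3]
  if (!any(inside)) return(0L)
  idx <- idx[inside, , drop = FALSE]
  nrow(unique(idx))
}

# Insert points so no segment exceeds `step` mm.
.densify <- function(pts, step) {
  seg <- sqrt(rowSums(diff(pts)^2))
  out <- vector("list", nrow(pts) - 1L)
  for (i in seq_len(nrow(pts) - 1L)) {
    k <- max(1L, ceiling(seg[i] / step))
    f <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- outer(1 - f, pts[i, ]) + outer(f, pts[i + 1L, ])
  }
  rbind(do.call(rbind, out), pts[nrow(pts), , drop = FALSE])
}
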