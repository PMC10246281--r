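# Synthetic phantoms: streamline bundles with known ground-truth
# parcels, FA-like scalar images, and two-group cohorts with a
# localized mean-shift or texture effect. These make the whole
# pipeline testable without imaging data.

#' Phantom bundle specification
#'
#' @param shape Bundle geometry: parallel `tube`, `fan` (common trunk
#'   for the first 60% of the length, then linearly diverging), or
#'   circular `arc`.
#' @param length_mm Bundle length along its course.
#' @param trunk_radius_mm Radius of the bundle cross-section.
#' @param fan_half_angle_deg Maximum divergence angle (fan only; 0
#'   degenerates to a tube).
#' @param n_streamlines Number of streamlines.
#' @param jitter_sd_mm Per-point Gaussian jitter (mm).
#' @param grid_shape Voxel grid dimensions.
#' @param voxel_size_mm Voxel spacing (mm), possibly anisotropic.
#' @param n_parcels Parcel count for the ground-truth labeling.
#' @param seed Integer seed; the bundle is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c("tube", "fan", "arc"), length_mm = 40,
                         trunk_radius_mm = 2, fan_half_angle_deg = 30,
                         n_streamlines = 200L, jitter_sd_mm = 0.2,
                         grid_shape = c(24L, 24L, 48L),
                         voxel_size_mm = c(1, 1, 1), n_parcels = 5L,
                         seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(length_mm > 0, trunk_radius_mm >= 0, fan_half_angle_deg >= 0,
            n_streamlines >= 1L, n_parcels >= 1L, all(grid_shape >= 2L))
  structure(list(shape = shape, length_mm = length_mm,
                 trunk_radius_mm = trunk_radius_mm,
                 fan_half_angle_deg = fan_half_angle_deg,
                 n_streamlines = as.integer(n_streamlines),
                 jitter_sd_mm = jitter_sd_mm,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_parcels = as.integer(n_parcels), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom bundle with ground truth
#'
#' Returns the tractogram, the tract envelope (streamline-visited
#' voxels dilated by one), a start-region ROI at the bundle origin, and
#' ground-truth parcel labels obtained by equal-arc-length binning of
#' each streamline rasterized to voxels (majority vote per voxel, ties
#' toward the lower label; envelope voxels without visits take the
#' label of the nearest labeled voxel).
#'
#' @param spec A [phantom_spec()].
#' @return List with `tractogram`, `envelope`, `start_roi`,
#'   `ground_truth` (a `label_image`), and `reference`.
#' @export
make_bundle <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  affine <- diag(c(spec$voxel_size_mm, 1))
  grid <- ref_grid(spec$grid_shape, affine)
  fov <- spec$grid_shape * spec$voxel_size_mm
  if (spec$length_mm > fov[3] - 2) stop("grid too small for bundle length")
  set.seed(spec$seed)
  n <- spec$n_streamlines
  cx <- fov[1] / 2; cy <- fov[2] / 2
  z0 <- (fov[3] - spec$length_mm) / 2
  step <- min(spec$voxel_size_mm)        # ~1 point per voxel along the course
  n_pts <- max(2L, ceiling(spec$length_mm / step) + 1L)
  tt <- seq(0, 1, length.out = n_pts)    # arc-length parameter
  # per-streamline cross-section offset, uniform in the trunk disk
  rr <- spec$trunk_radius_mm * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  ox <- rr * cos(th); oy <- rr * sin(th)
  fan_angle <- runif(n, -1, 1) * spec$fan_half_angle_deg * pi / 180
  streamlines <- vector("list", n)
  for (i in seq_len(n)) {
    base <- switch(spec$shape,
      tube = cbind(cx + ox[i], cy + oy[i], z0 + tt * spec$length_mm),
      fan = {
        z <- z0 + tt * spec$length_mm
        x <- rep(cx + ox[i], n_pts)
        past <- tt > 0.6                 # diverge after 60% of the course
        x[past] <- x[past] + tan(fan_angle[i]) * (tt[past] - 0.6) * spec$length_mm
        cbind(x, cy + oy[i], z)
      },
      arc = {
        # quarter-circle arc in the x-z plane with arc length = length_mm
        R <- spec$length_mm / (pi / 2)
        ang <- tt * pi / 2
        cbind(cx - R / 2 + (R + ox[i]) * cos(ang), cy + oy[i],
              z0 + (R + ox[i]) * sin(ang))
      })
    jit <- matrix(rnorm(length(base), sd = spec$jitter_sd_mm), ncol = 3)
    pts <- base + jit
    # jitter may not create duplicate consecutive points in practice,
    # but guard the invariant
    seg0 <- which(rowSums(diff(pts)^2) == 0)
    if (length(seg0)) pts <- pts[-(seg0 + 1L), , drop = FALSE]
    streamlines[[i]] <- streamline(pts)
  }
  tg <- tractogram(streamlines, grid)
  # rasterize visits with equal-arc-length parcel labels
  votes <- vector("list", n)
  for (i in seq_len(n)) {
    s <- unclass(streamlines[[i]])
    dense <- .densify(s, min(spec$voxel_size_mm) / 2)
    seg <- sqrt(rowSums(diff(dense)^2))
    arc <- c(0, cumsum(seg))
    lab <- pmin(spec$n_parcels,
                floor(arc / arc[length(arc)] * spec$n_parcels) + 1L)
    idx <- .round_index(world_to_index(affine, dense))
    inside <- idx[, 1] >= 0 & idx[, 1] < spec$grid_shape[1] &
      idx[, 2] >= 0 & idx[, 2] < spec$grid_shape[2] &
      idx[, 3] >= 0 & idx[, 3] < spec$grid_shape[3]
    votes[[i]] <- cbind(idx[inside, , drop = FALSE], lab[inside])
  }
  votes <- do.call(rbind, votes)
  lin <- votes[, 1] + spec$grid_shape[1] *
    (votes[, 2] + spec$grid_shape[2] * votes[, 3]) + 1
  visited <- array(0L, spec$grid_shape)
  visited[unique(lin)] <- 1L
  # majority vote per voxel; ties toward the lower label
  gt <- array(0L, spec$grid_shape)
  tab <- table(lin, votes[, 4])
  win <- apply(tab, 1, function(r) which.max(r))    # first max = lower label
  gt[as.numeric(rownames(tab))] <- as.integer(colnames(tab))[win]
  env <- .dilate26(visited)
  # propagate labels into dilation-only envelope voxels
  gt <- .fill_labels(gt, env)
  roi <- array(0L, spec$grid_shape)
  starts <- do.call(rbind, lapply(streamlines, function(s) s[1, , drop = FALSE]))
  sidx <- .round_index(world_to_index(affine, starts))
  ok <- sidx[, 1] >= 0 & sidx[, 1] < spec$grid_shape[1] &
    sidx[, 2] >= 0 & sidx[, 2] < spec$grid_shape[2] &
    sidx[, 3] >= 0 & sidx[, 3] < spec$grid_shape[3]
  roi[sidx[ok, , drop = FALSE] + 1L] <- 1L
  roi <- .dilate26(roi)
  list(tractogram = tg,
       envelope = binary_mask(env, affine),
       start_roi = binary_mask(roi, affine),
       ground_truth = label_image(gt, affine, n_parcels = spec$n_parcels),
       reference = grid)
}

# 26-connected binary dilation by one voxel.
.dilate26 <- function(a) {
  out <- a
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (!dx && !dy && !dz) next
    out <- pmax(out, .shift_zero(a, dx, dy, dz))
  }
  out
}

.shift_zero <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0L, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# Assign unlabeled envelope voxels the label of the nearest labeled
# voxel by iterative 26-neighbor propagation (ties toward lower label).
.fill_labels <- function(gt, env) {
  repeat {
    todo <- env == 1L & gt == 0L
    if (!any(todo)) break
    best <- array(Inf, dim(gt))
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (!dx && !dy && !dz) next
      nb <- .shift_zero(gt, dx, dy, dz)
      cand <- todo & nb > 0L
      best[cand] <- pmin(best[cand], nb[cand])
    }
    got <- is.finite(best)
    if (!any(got)) break                   # disconnected remainder
    gt[got] <- as.integer(best[got])
  }
  gt[env == 0L] <- 0L
  gt
}

#' Cohort specification for two-group experiments
#'
#' @param n_per_group Subjects per group.
#' @param effect `"mean_shift"` (group B gets +delta inside the effect
#'   parcel) or `"texture"` (group B's noise standard deviation inside
#'   the effect parcel is multiplied by `rho`, re-centered so parcel
#'   means match group A).
#' @param delta Mean shift (FA units).
#' @param rho Noise sd ratio (>= 1).
#' @param effect_parcel Parcel index k carrying the group difference.
#' @param noise_sd White-noise sd added to the smooth background.
#' @param bg_range Background intensity range after smoothing.
#' @param smooth_mm Gaussian kernel (mm) of the smooth background field.
#' @param seed Cohort seed; everything is reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 25L,
                        effect = c("texture", "mean_shift"),
                        delta = 0.1, rho = 2, effect_parcel = 3L,
                        noise_sd = 0.03, bg_range = c(0.3, 0.7),
                        smooth_mm = 4, seed = 1L) {
  effect <- match.arg(effect)
  stopifnot(delta >= 0, rho >= 1, n_per_group >= 1L, effect_parcel >= 1L)
  structure(list(n_per_group = as.integer(n_per_group), effect = effect,
                 delta = delta, rho = rho,
                 effect_parcel = as.integer(effect_parcel),
                 noise_sd = noise_sd, bg_range = bg_range,
                 smooth_mm = smooth_mm, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one subject's FA-like image
#'
#' Background = Gaussian-smoothed white noise rescaled to `bg_range`
#' plus white noise, clipped to [0, 1]; group B additionally carries
#' the cohort's effect inside the ground-truth effect parcel.
#'
#' @param bundle Output of [make_bundle()].
#' @param group `"A"` or `"B"`.
#' @param cohort A [cohort_spec()].
#' @param subject_seed Per-subject seed.
#' @return A `scalar_image`.
#' @export
make_subject_image <- function(bundle, group, cohort, subject_seed) {
  gt <- bundle$ground_truth
  k <- cohort$effect_parcel
  if (k > gt$n_parcels) stop("effect parcel not present in ground truth")
  d <- dim(gt$data)
  vs <- gt$voxel_size
  set.seed(subject_seed)
  bg <- array(rnorm(prod(d)), d)
  for (ax in 1:3) bg <- .gauss_axis(bg, cohort$smooth_mm / vs[ax], ax)
  rng <- range(bg)
  bg <- cohort$bg_range[1] +
    (bg - rng[1]) / (rng[2] - rng[1]) * diff(cohort$bg_range)
  noise <- array(rnorm(prod(d), sd = cohort$noise_sd), d)
  img <- bg + noise
  sel <- gt$data == k
  if (group == "B") {
    if (cohort$effect == "mean_shift") {
      img[sel] <- img[sel] + cohort$delta
    } else {
      extra <- rnorm(sum(sel), sd = cohort$noise_sd * cohort$rho)
      img[sel] <- bg[sel] + (extra - mean(extra) + mean(noise[sel]))
    }
  }
  scalar_image(pmin(pmax(img, 0), 1), gt$affine)
}

#' Generate a balanced two-group phantom cohort
#'
#' Each subject gets an independently jittered bundle (same geometry
#' spec) and an image carrying the group effect. Fully reproducible
#' from the cohort seed.
#'
#' @param cohort A [cohort_spec()].
#' @param phantom A [phantom_spec()]; its seed is re-derived per subject.
#' @return List of subjects: `id`, `group`, `tractogram`, `image`,
#'   `envelope`, `start_roi`, `ground_truth`.
#' @export
make_cohort <- function(cohort, phantom) {
  n <- 2L * cohort$n_per_group
  groups <- rep(c("A", "B"), each = cohort$n_per_group)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    pspec <- phantom
    pspec$seed <- cohort$seed * 10000L + i
    bundle <- make_bundle(pspec)
    img <- make_subject_image(bundle, groups[i], cohort,
                              subject_seed = cohort$seed * 10000L + 5000L + i)
    subjects[[i]] <- list(id = sprintf("sub-%03d", i), group = groups[i],
                          tractogram = bundle$tractogram, image = img,
                          envelope = bundle$envelope,
                          start_roi = bundle$start_roi,
                          ground_truth = bundle$ground_truth)
  }
  subjects
}
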