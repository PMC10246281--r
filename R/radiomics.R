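# Radiomic feature families: intensity discretization, first-order
# statistics, 3-D shape descriptors, and the five gray-level
# texture-matrix families (GLCM, GLRLM, GLSZM, GLDM, NGTDM), following
# the standard published definitions. Family sizes are fixed by the
# registry: 18 + 22 + 16 + 16 + 14 + 5 = 91 per image variant, plus 14
# shape features on the original geometry.

.EPS <- 2.2e-16

#' Discretize intensities into equal-width bins
#'
#' Fixed-bin-count mode: `n_bins` equal-width bins over the value range
#' of the parcel; the maximum maps to bin `n_bins`; constant input maps
#' to bin 1. Range-relative binning makes downstream texture features
#' invariant to adding a constant to the image.
#'
#' @param values Numeric vector (>= 1 value).
#' @param n_bins Number of gray levels (default 32).
#' @return Integer bin labels in 1..n_bins.
#' @export
discretize_intensities <- function(values, n_bins = 32L) {
  if (length(values) == 0L) stop("no values to discretize")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  w <- (rng[2] - rng[1]) / n_bins
  pmin(as.integer(floor((values - rng[1]) / w)) + 1L, as.integer(n_bins))
}

#' First-order intensity features
#'
#' The 18 standard first-order features. Entropy and uniformity are
#' computed on the discretized values; all others on the raw
#' intensities. Degenerate moments of constant input are defined as 0
#' (skewness, kurtosis).
#'
#' @param values Numeric vector of parcel intensities.
#' @param voxel_volume Volume of one voxel in mm^3 (for total energy).
#' @param n_bins Discretization levels for entropy/uniformity.
#' @return Named numeric vector of length 18.
#' @export
compute_first_order <- function(values, voxel_volume = 1, n_bins = 32L) {
  n <- length(values)
  d <- discretize_intensities(values, n_bins)
  p <- tabulate(d, nbins = max(d)) / n
  p <- p[p > 0]
  m <- mean(values)
  cen <- values - m
  m2 <- mean(cen^2)
  q <- unname(quantile(values, c(0.10, 0.25, 0.5, 0.75, 0.90), type = 7))
  robust <- values[values >= q[1] & values <= q[5]]
  c(firstorder_Energy = sum(values^2),
    firstorder_TotalEnergy = voxel_volume * sum(values^2),
    firstorder_Entropy = -sum(p * log2(p + .EPS)),
    firstorder_Minimum = min(values),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[5],
    firstorder_Maximum = max(values),
    firstorder_Mean = m,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(values) - min(values),
    firstorder_MeanAbsoluteDeviation = mean(abs(cen)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(values^2)),
    firstorder_Skewness = if (m2 > 0) mean(cen^3) / m2^1.5 else 0,
    firstorder_Kurtosis = if (m2 > 0) mean(cen^4) / m2^2 else 0,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2))
}

# ---- shape -----------------------------------------------------------------

#' 3-D shape features of a parcel
#'
#' The 14 standard shape descriptors, independent of image intensities.
#' Surface area and mesh volume come from a watertight iso-surface
#' (marching tetrahedra at iso 0.5 on the binary parcel); axis lengths
#' from the eigenvalues of the voxel-center covariance. Single-voxel
#' parcels fall back to voxel-based surrogates.
#'
#' @param mask Logical/0-1 3-D array marking the parcel.
#' @param voxel_size Numeric length-3 voxel spacing in mm.
#' @return Named numeric vector of length 14.
#' @export
compute_shape <- function(mask, voxel_size = c(1, 1, 1)) {
  mask <- mask != 0
  nv <- sum(mask)
  if (nv == 0L) stop("empty parcel")
  vox_vol <- prod(voxel_size)
  if (nv > 1L) {
    mesh <- .marching_tets(mask, voxel_size)
    surf <- mesh$area
    mvol <- mesh$volume
  } else {
    surf <- 0; mvol <- 0
  }
  if (surf <= 0) {       # single-voxel parcel: voxel-based surrogates
    surf <- 2 * (voxel_size[1] * voxel_size[2] + voxel_size[1] * voxel_size[3] +
                   voxel_size[2] * voxel_size[3]) * nv
    mvol <- nv * vox_vol
  }
  idx <- which(mask, arr.ind = TRUE) - 1
  phys <- sweep(idx, 2, voxel_size, "*")
  cov3 <- if (nv > 1) stats::cov(phys) * (nv - 1) / nv else matrix(0, 3, 3)
  ev <- sort(pmax(eigen(cov3, symmetric = TRUE)$values, 0), decreasing = TRUE)
  axis_len <- 4 * sqrt(ev)
  d3 <- .max_pairwise_diameter(phys, voxel_size)
  sphericity <- (36 * pi * mvol^2)^(1 / 3) / surf
  c(shape_MeshVolume = mvol,
    shape_VoxelVolume = nv * vox_vol,
    shape_SurfaceArea = surf,
    shape_SurfaceVolumeRatio = surf / mvol,
    shape_Sphericity = sphericity,
    shape_Maximum3DDiameter = d3$d3,
    shape_Maximum2DDiameterSlice = d3$slice,
    shape_Maximum2DDiameterColumn = d3$column,
    shape_Maximum2DDiameterRow = d3$row,
    shape_MajorAxisLength = axis_len[1],
    shape_MinorAxisLength = axis_len[2],
    shape_LeastAxisLength = axis_len[3],
    shape_Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    shape_Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

# Max pairwise distances between boundary voxel centers: full 3-D and
# in the three coordinate planes (slice = x-y, column = x-z, row = y-z).
.max_pairwise_diameter <- function(phys, voxel_size) {
  # thin to boundary-ish set if large
  if (nrow(phys) > 1500L) {
    ch <- unique(rbind(
      phys[order(phys[, 1]), ][c(1, nrow(phys)), ],
      phys[chull_like(phys), , drop = FALSE]))
    phys <- ch
  }
  pd2 <- function(m) {
    if (nrow(m) < 2L) return(0)
    g <- as.matrix(dist(m))
    max(g)
  }
  list(d3 = pd2(phys),
       slice = pd2(phys[, c(1, 2), drop = FALSE]),
       column = pd2(phys[, c(1, 3), drop = FALSE]),
       row = pd2(phys[, c(2, 3), drop = FALSE]))
}

# Cheap hull-ish subset: extreme points along many random directions.
chull_like <- function(phys) {
  set.seed(0L)
  dirs <- matrix(rnorm(3 * 200), ncol = 3)
  proj <- phys %*% t(dirs)
  unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
}

# Marching tetrahedra on the binary field sampled at voxel centers,
# using the body-centered 24-tet split of each 2x2x2 cell: every face
# contributes four tetrahedra (edge, face center, body center) whose
# center values are interpolated corner means, which places iso-surface
# vertices sub-voxel accurately and avoids the staircase bias of a
# purely binary mesh. The surface is watertight; the enclosed mesh
# volume follows from the divergence theorem over the oriented
# triangles.
.marching_tets <- function(mask, voxel_size) {
  d <- dim(mask)
  pad <- array(0, d + 4L)
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- mask
  # mild face-neighbor smoothing: symmetric, so planar boundaries keep
  # their 0.5-crossing exactly while staircase corners are rounded;
  # center weight 8 keeps isolated voxels (8/14 > 1/2) meshable
  sm <- 8 * pad
  for (ax in 1:3) {
    sm <- sm + .shift_replicate(pad, 1L, ax) + .shift_replicate(pad, -1L, ax)
  }
  pad <- sm / 14
  cand <- .mixed_cells(pad > 0.5)
  if (nrow(cand) == 0L) return(list(area = 0, volume = 0))
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces: axis, side, corner indices in cyclic order
  faces <- list()
  for (ax in 1:3) for (side in 0:1) {
    ids <- which(corners[, ax] == side)
    o <- corners[ids, -ax, drop = FALSE]
    ord <- order(atan2(o[, 2] - 0.5, o[, 1] - 0.5))
    faces[[length(faces) + 1L]] <- ids[ord]
  }
  area <- 0; vol6 <- 0
  for (ci in seq_len(nrow(cand))) {
    base <- cand[ci, ]
    pts <- sweep(sweep(corners, 2, base, "+") - 1.5, 2, voxel_size, "*")
    vals <- pad[cbind(base[1] + corners[, 1], base[2] + corners[, 2],
                      base[3] + corners[, 3])]
    cval <- mean(vals)
    cpt <- colMeans(pts)
    for (f in faces) {
      fval <- mean(vals[f])
      fpt <- colMeans(pts[f, , drop = FALSE])
      for (e in 1:4) {
        a <- f[e]; b <- f[if (e == 4L) 1L else e + 1L]
        tv <- c(vals[a], vals[b], fval, cval)
        tp <- rbind(pts[a, ], pts[b, ], fpt, cpt)
        res <- .tet_iso(tv, tp)
        area <- area + res$area
        vol6 <- vol6 + res$vol6
      }
    }
  }
  list(area = area, volume = abs(vol6) / 6)
}

# Iso-0.5 surface piece of one tetrahedron with linearly interpolated
# vertex values; returns the triangle area and the signed divergence
# contribution (outward orientation, normals away from the
# above-threshold region).
.tet_iso <- function(v, p, t = 0.5) {
  above <- v > t
  na <- sum(above)
  if (na == 0L || na == 4L) return(list(area = 0, vol6 = 0))
  cut <- function(i, j) {
    s <- (t - v[i]) / (v[j] - v[i])
    p[i, ] + s * (p[j, ] - p[i, ])
  }
  if (na == 1L || na == 3L) {
    apex <- if (na == 1L) which(above) else which(!above)
    oth <- setdiff(1:4, apex)
    q1 <- cut(apex, oth[1]); q2 <- cut(apex, oth[2]); q3 <- cut(apex, oth[3])
    ref <- if (na == 1L) p[apex, ] else p[oth[1], ]  # a point above iso
    .orient_tris(list(rbind(q1, q2, q3)), ref)
  } else {
    ins <- which(above); outs <- which(!above)
    q1 <- cut(ins[1], outs[1]); q2 <- cut(ins[1], outs[2])
    q3 <- cut(ins[2], outs[2]); q4 <- cut(ins[2], outs[1])
    .orient_tris(list(rbind(q1, q2, q3), rbind(q1, q3, q4)), p[ins[1], ])
  }
}

# Orient triangles so normals point away from `ref` (inside the
# region); accumulate area and signed volume (6x) via the divergence
# theorem.
.orient_tris <- function(tris, ref) {
  area <- 0; vol6 <- 0
  for (tr in tris) {
    u <- tr[2, ] - tr[1, ]; w <- tr[3, ] - tr[1, ]
    nrm <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
             u[1] * w[2] - u[2] * w[1])
    a2 <- sqrt(sum(nrm^2))
    area <- area + a2 / 2
    if (sum(nrm * (tr[1, ] - ref)) < 0) {
      tr <- tr[c(1, 3, 2), ]
    }
    vol6 <- vol6 + sum(tr[1, ] * c(
      tr[2, 2] * tr[3, 3] - tr[2, 3] * tr[3, 2],
      tr[2, 3] * tr[3, 1] - tr[2, 1] * tr[3, 3],
      tr[2, 1] * tr[3, 2] - tr[2, 2] * tr[3, 1]))
  }
  list(area = area, vol6 = vol6)
}

# Cells (2x2x2 corner blocks) with mixed in/out corners; returns base
# corner indices into the padded array.
.mixed_cells <- function(pad) {
  d <- dim(pad)
  s <- function(dx, dy, dz)
    pad[(1 + dx):(d[1] - 1 + dx), (1 + dy):(d[2] - 1 + dy),
        (1 + dz):(d[3] - 1 + dz)]
  acc <- array(0L, d - 1L)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    acc <- acc + s(dx, dy, dz)
  which(acc > 0L & acc < 8L, arr.ind = TRUE)
}

.full_cells <- function(pad) {
  d <- dim(pad)
  s <- function(dx, dy, dz)
    pad[(1 + dx):(d[1] - 1 + dx), (1 + dy):(d[2] - 1 + dy),
        (1 + dz):(d[3] - 1 + dz)]
  acc <- array(0L, d - 1L)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    acc <- acc + s(dx, dy, dz)
  sum(acc == 8L)
}

# ---- texture families ------------------------------------------------------

#' Texture-matrix features of a discretized parcel
#'
#' Builds the requested family's gray-level matrix over 26-connected
#' 3-D offsets (GLCM and GLRLM are computed per direction over the 13
#' unique directions and the features averaged) and returns the
#' standard named features. Family sizes: GLCM 22, GLRLM 16, GLSZM 16,
#' GLDM 14, NGTDM 5.
#'
#' @param family One of "glcm", "glrlm", "glszm", "gldm", "ngtdm".
#' @param disc Integer 3-D array: 0 outside the parcel, bin labels
#'   1..n_bins inside (see [discretize_intensities()]).
#' @param gldm_alpha Dependence tolerance for GLDM (default 0).
#' @return Named numeric vector.
#' @export
compute_texture_family <- function(family, disc,
                                   gldm_alpha = 0L) {
  family <- match.arg(family, c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
  dims <- dim(disc)
  storage.mode(disc) <- "integer"
  levels_present <- sort(unique(disc[disc > 0]))
  if (length(levels_present) == 0L) stop("empty parcel")
  nlev <- max(levels_present)
  np <- sum(disc > 0)
  switch(family,
         glcm = .glcm_features(glcm_cpp(disc, dims, nlev), levels_present),
         glrlm = .glrlm_features(glrlm_cpp(disc, dims, nlev), levels_present, np),
         glszm = .glszm_features(glszm_cpp(disc, dims, nlev), levels_present, np),
         gldm = .gldm_features(gldm_cpp(disc, dims, nlev, as.integer(gldm_alpha)),
                               levels_present, np),
         ngtdm = .ngtdm_features(ngtdm_cpp(disc, dims, nlev), levels_present))
}

.glcm_features <- function(counts, levels) {
  nd <- dim(counts)[3]
  acc <- NULL
  for (d in seq_len(nd)) {
    M <- counts[levels, levels, d, drop = FALSE][, , 1]
    if (!is.matrix(M)) M <- matrix(M, length(levels), length(levels))
    if (sum(M) == 0) next
    f <- .glcm_one(M / sum(M), levels)
    acc <- if (is.null(acc)) rbind(f) else rbind(acc, f)
  }
  if (is.null(acc)) {     # single voxel: no co-occurrences at all
    nm <- names(.glcm_one(matrix(1, 1, 1), 1))
    return(setNames(rep(0, length(nm)), nm))
  }
  colMeans(acc)
}

.glcm_one <- function(P, levels) {
  ng <- length(levels)
  i <- matrix(levels, ng, ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(levels * px); muy <- sum(levels * py)
  sigx <- sqrt(sum((levels - mux)^2 * px)); sigy <- sqrt(sum((levels - muy)^2 * py))
  kdiff <- abs(i - j)
  ksum <- i + j
  pxy_diff <- tapply(P, kdiff, sum)
  kd <- as.numeric(names(pxy_diff))
  pxy_sum <- tapply(P, ksum, sum)
  ks <- as.numeric(names(pxy_sum))
  da <- sum(kd * pxy_diff)
  HX <- -sum(px * log2(px + .EPS)); HY <- -sum(py * log2(py + .EPS))
  HXY <- -sum(P * log2(P + .EPS))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P * log2(pxpy + .EPS))
  HXY2 <- -sum(pxpy * log2(pxpy + .EPS))
  corr <- if (sigx > 0 && sigy > 0)
    (sum(i * j * P) - mux * muy) / (sigx * sigy) else 1
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  iv_mask <- kdiff > 0
  c(glcm_Autocorrelation = sum(i * j * P),
    glcm_JointAverage = mux,
    glcm_ClusterProminence = sum((ksum - mux - muy)^4 * P),
    glcm_ClusterShade = sum((ksum - mux - muy)^3 * P),
    glcm_ClusterTendency = sum((ksum - mux - muy)^2 * P),
    glcm_Contrast = sum((i - j)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(pxy_diff * log2(pxy_diff + .EPS)),
    glcm_DifferenceVariance = sum((kd - da)^2 * pxy_diff),
    glcm_Id = sum(P / (1 + kdiff)),
    glcm_Idm = sum(P / (1 + kdiff^2)),
    glcm_Idmn = sum(P / (1 + (kdiff / ng)^2)),
    glcm_Idn = sum(P / (1 + kdiff / ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(P[iv_mask] / kdiff[iv_mask]^2),
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = HXY,
    glcm_MCC = .glcm_mcc(P, px, py),
    glcm_MaximumProbability = max(P),
    glcm_SumEntropy = -sum(pxy_sum * log2(pxy_sum + .EPS)))
}

.glcm_mcc <- function(P, px, py) {
  ng <- nrow(P)
  if (ng == 1L) return(1)
  nz <- px > 0
  P2 <- P[nz, nz, drop = FALSE]
  pxz <- px[nz]; pyz <- py[nz]
  Q <- matrix(0, sum(nz), sum(nz))
  for (k in seq_len(sum(nz))) {
    Q <- Q + outer(P2[, k], P2[, k]) / (pxz %o% rep(pyz[k], sum(nz)))
  }
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2L) return(1)
  sqrt(max(0, min(1, ev[2])))
}

.glrlm_features <- function(counts, levels, np) {
  nd <- dim(counts)[3]
  acc <- NULL
  for (d in seq_len(nd)) {
    M <- counts[levels, , d, drop = FALSE][, , 1]
    if (!is.matrix(M)) M <- matrix(M, length(levels), dim(counts)[2])
    f <- .rl_features(M, levels, np, prefix = "glrlm",
                      names_map = c("ShortRunEmphasis", "LongRunEmphasis",
                                    "GrayLevelNonUniformity",
                                    "GrayLevelNonUniformityNormalized",
                                    "RunLengthNonUniformity",
                                    "RunLengthNonUniformityNormalized",
                                    "RunPercentage", "GrayLevelVariance",
                                    "RunVariance", "RunEntropy",
                                    "LowGrayLevelRunEmphasis",
                                    "HighGrayLevelRunEmphasis",
                                    "ShortRunLowGrayLevelEmphasis",
                                    "ShortRunHighGrayLevelEmphasis",
                                    "LongRunLowGrayLevelEmphasis",
                                    "LongRunHighGrayLevelEmphasis"))
    acc <- if (is.null(acc)) rbind(f) else rbind(acc, f)
  }
  colMeans(acc)
}

.glszm_features <- function(counts, levels, np) {
  M <- counts[levels, , drop = FALSE]
  .rl_features(M, levels, np, prefix = "glszm",
               names_map = c("SmallAreaEmphasis", "LargeAreaEmphasis",
                             "GrayLevelNonUniformity",
                             "GrayLevelNonUniformityNormalized",
                             "SizeZoneNonUniformity",
                             "SizeZoneNonUniformityNormalized",
                             "ZonePercentage", "GrayLevelVariance",
                             "ZoneVariance", "ZoneEntropy",
                             "LowGrayLevelZoneEmphasis",
                             "HighGrayLevelZoneEmphasis",
                             "SmallAreaLowGrayLevelEmphasis",
                             "SmallAreaHighGrayLevelEmphasis",
                             "LargeAreaLowGrayLevelEmphasis",
                             "LargeAreaHighGrayLevelEmphasis"))
}

# Shared run-length / size-zone feature kernel: M is levels x sizes.
.rl_features <- function(M, levels, np, prefix, names_map) {
  Nr <- sum(M)
  if (Nr == 0) {
    out <- rep(0, 16)
    names(out) <- paste(prefix, names_map, sep = "_")
    return(out)
  }
  jv <- seq_len(ncol(M))
  iv <- levels
  p <- M / Nr
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(iv * pi_); mu_j <- sum(jv * pj)
  out <- c(sum(t(p) / jv^2), sum(t(p) * jv^2),
           sum(rowSums(M)^2) / Nr, sum(rowSums(M)^2) / Nr^2,
           sum(colSums(M)^2) / Nr, sum(colSums(M)^2) / Nr^2,
           Nr / np,
           sum(pi_ * (iv - mu_i)^2),
           sum(pj * (jv - mu_j)^2),
           -sum(p[p > 0] * log2(p[p > 0] + .EPS)),
           sum(p / iv^2), sum(p * iv^2),
           sum(sweep(p, 2, jv^2, "/") / iv^2),
           sum(sweep(p, 2, jv^2, "/") * iv^2),
           sum(sweep(p, 2, jv^2, "*") / iv^2),
           sum(sweep(p, 2, jv^2, "*") * iv^2))
  names(out) <- paste(prefix, names_map, sep = "_")
  out
}

.gldm_features <- function(counts, levels, np) {
  M <- counts[levels, , drop = FALSE]
  jv <- 1:27                     # dependence j = neighbor count + 1
  Nz <- sum(M)
  p <- M / Nz
  pi_ <- rowSums(p); pj <- colSums(p)
  iv <- levels
  mu_i <- sum(iv * pi_); mu_j <- sum(jv * pj)
  c(gldm_SmallDependenceEmphasis = sum(t(p) / jv^2),
    gldm_LargeDependenceEmphasis = sum(t(p) * jv^2),
    gldm_GrayLevelNonUniformity = sum(rowSums(M)^2) / Nz,
    gldm_DependenceNonUniformity = sum(colSums(M)^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(colSums(M)^2) / Nz^2,
    gldm_GrayLevelVariance = sum(pi_ * (iv - mu_i)^2),
    gldm_DependenceVariance = sum(pj * (jv - mu_j)^2),
    gldm_DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0] + .EPS)),
    gldm_LowGrayLevelEmphasis = sum(p / iv^2),
    gldm_HighGrayLevelEmphasis = sum(p * iv^2),
    gldm_SmallDependenceLowGrayLevelEmphasis =
      sum(sweep(p, 2, jv^2, "/") / iv^2),
    gldm_SmallDependenceHighGrayLevelEmphasis =
      sum(sweep(p, 2, jv^2, "/") * iv^2),
    gldm_LargeDependenceLowGrayLevelEmphasis =
      sum(sweep(p, 2, jv^2, "*") / iv^2),
    gldm_LargeDependenceHighGrayLevelEmphasis =
      sum(sweep(p, 2, jv^2, "*") * iv^2))
}

.ngtdm_features <- function(acc, levels) {
  ni <- acc[levels, 1]
  si <- acc[levels, 2]
  nvp <- sum(ni)
  present <- ni > 0
  iv <- levels[present]
  ni <- ni[present]; si <- si[present]
  pi_ <- ni / nvp
  ngp <- length(iv)
  coarse_den <- sum(pi_ * si)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    ii <- outer(iv, iv, "-")^2
    pp <- outer(pi_, pi_)
    contrast <- sum(pp * ii) / (ngp * (ngp - 1)) * sum(si) / nvp
    busy_den <- sum(abs(outer(iv * pi_, iv * pi_, "-")))
    busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
    psum <- outer(pi_, pi_, "+")
    snum <- outer(pi_ * si, pi_ * si, "+")
    complexity <- sum(abs(outer(iv, iv, "-")) * snum / psum) / nvp
    strength_den <- sum(si)
    strength <- if (strength_den > 0) sum(psum * ii) / strength_den else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}
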