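# Shared fixture builders for the test suite. Everything is generated
# in code under fixed seeds; no binary data ships with the package.

# Random blob parcels used by the feature-oracle tests: a digitized
# ball with random voxels toggled, intensities uniform in [0, 1].
oracle_parcel <- function(id, dim3 = c(7L, 7L, 7L)) {
  set.seed(1000L + id)
  ctr <- (dim3 + 1) / 2
  idx <- as.matrix(expand.grid(seq_len(dim3[1]), seq_len(dim3[2]),
                               seq_len(dim3[3])))
  d2 <- rowSums(sweep(idx, 2, ctr)^2)
  mask <- array(d2 <= 2.6^2, dim3)
  flip <- array(runif(prod(dim3)) < 0.06, dim3)
  mask <- mask | flip
  values <- array(runif(prod(dim3)), dim3)
  list(mask = mask, values = values)
}

# Straight-tube phantom with its analytic equal-slab parcellation
# (derived from the generating geometry, not from the envelope).
tube_with_slabs <- function(seed = 3L, n = 5L) {
  spec <- phantom_spec("tube", seed = seed, n_parcels = n)
  b <- make_bundle(spec)
  fov <- spec$grid_shape * spec$voxel_size_mm
  z0 <- (fov[3] - spec$length_mm) / 2
  idx <- which(b$envelope$data > 0, arr.ind = TRUE)
  z <- (idx[, 3] - 1) * spec$voxel_size_mm[3]
  slab <- pmin(n, pmax(1L, floor((z - z0) / (spec$length_mm / n)) + 1L))
  arr <- array(0L, dim(b$envelope$data))
  arr[idx] <- slab
  list(bundle = b, spec = spec,
       slabs = label_image(arr, b$envelope$affine, n_parcels = n))
}
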