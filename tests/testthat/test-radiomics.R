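# Feature families: discretization, first-order, shape, and the five
# texture-matrix families.

test_that("discretization uses equal-width bins with max in the top bin", {
  expect_equal(discretize_intensities(rep(3.7, 5)), rep(1L, 5))
  ramp <- seq(0, 1, length.out = 128)
  d <- discretize_intensities(ramp, 4)
  expect_equal(tabulate(d, 4), rep(32L, 4))
  expect_equal(d[128], 4L)
  vals <- c(0.1, 0.5, 0.9)
  expect_equal(discretize_intensities(vals, 8)[3], 8L)
})

test_that("first-order features match direct computation", {
  fo <- compute_first_order(c(1, 2, 3))
  expect_equal(unname(fo["firstorder_Energy"]), 14)
  expect_equal(unname(fo["firstorder_Mean"]), 2)
  expect_equal(unname(fo["firstorder_Variance"]), 2 / 3)
  expect_equal(unname(fo["firstorder_RootMeanSquared"]), sqrt(14 / 3))
  expect_length(fo, 18L)
  const <- compute_first_order(rep(5, 10))
  expect_equal(unname(const["firstorder_Mean"]), 5)
  expect_equal(unname(const["firstorder_Variance"]), 0)
  expect_equal(unname(const["firstorder_Entropy"]), 0, tolerance = 1e-12)
  expect_equal(unname(const["firstorder_Uniformity"]), 1)
  expect_equal(unname(const["firstorder_Skewness"]), 0)
  # total energy scales with voxel volume
  fo2 <- compute_first_order(c(1, 2, 3), voxel_volume = 2)
  expect_equal(unname(fo2["firstorder_TotalEnergy"]), 28)
})

test_that("first-order location stats ignore discretization settings", {
  set.seed(21)
  v <- rnorm(200)
  a <- compute_first_order(v, n_bins = 8)
  b <- compute_first_order(v, n_bins = 64)
  for (nm in c("firstorder_Mean", "firstorder_Median", "firstorder_Minimum",
               "firstorder_Maximum", "firstorder_Variance"))
    expect_equal(a[nm], b[nm])
  expect_false(isTRUE(all.equal(a["firstorder_Entropy"],
                                b["firstorder_Entropy"])))
})

test_that("shape features: voxel surrogates, ball, and intensity independence", {
  sh1 <- compute_shape(array(1, c(1, 1, 1)))
  expect_length(sh1, 14L)
  expect_equal(unname(sh1["shape_VoxelVolume"]), 1)
  expect_equal(unname(sh1["shape_SurfaceArea"]), 6)
  # anisotropic single voxel
  sh1a <- compute_shape(array(1, c(1, 1, 1)), voxel_size = c(1, 1, 2))
  expect_equal(unname(sh1a["shape_VoxelVolume"]), 2)
  # digitized ball of radius 8
  r <- 8; n <- 2 * r + 3; ctr <- (n + 1) / 2
  m <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r^2) m[i, j, k] <- 1
  sh <- compute_shape(m)
  expect_gte(unname(sh["shape_Sphericity"]), 0.9)
  expect_lte(unname(sh["shape_Sphericity"]), 1.0)
  expect_equal(unname(sh["shape_MeshVolume"]), 4 / 3 * pi * r^3,
               tolerance = 0.05)
  expect_equal(unname(sh["shape_Maximum3DDiameter"]), 16, tolerance = 0.1)
  expect_equal(unname(sh["shape_Elongation"]), 1, tolerance = 0.05)
  expect_error(compute_shape(array(0, c(3, 3, 3))), "empty")
})

test_that("elongated box has the expected axis ordering", {
  m <- array(0, c(12, 6, 6)); m[2:11, 2:4, 2:4] <- 1
  sh <- compute_shape(m)
  expect_gt(unname(sh["shape_MajorAxisLength"]),
            unname(sh["shape_MinorAxisLength"]))
  expect_gte(unname(sh["shape_MinorAxisLength"]),
             unname(sh["shape_LeastAxisLength"]))
  expect_lt(unname(sh["shape_Flatness"]), 1)
  expect_equal(unname(sh["shape_VoxelVolume"]), 90)
  expect_equal(unname(sh["shape_Maximum2DDiameterRow"]),
               sqrt(2^2 + 2^2), tolerance = 1e-10)   # y-z plane
})

test_that("texture families: constants, checkerboard, and family sizes", {
  disc <- array(0L, c(4, 4, 4)); disc[2:3, 2:3, 2:3] <- 1L
  g <- compute_texture_family("glcm", disc)
  expect_equal(unname(g["glcm_Contrast"]), 0)
  expect_equal(unname(g["glcm_Correlation"]), 1)
  expect_equal(unname(g["glcm_JointEnergy"]), 1)
  n <- compute_texture_family("ngtdm", disc)
  expect_equal(unname(n["ngtdm_Busyness"]), 0)
  expect_equal(unname(n["ngtdm_Contrast"]), 0)
  r <- compute_texture_family("glrlm", disc)
  expect_equal(unname(r["glrlm_GrayLevelNonUniformityNormalized"]), 1)
  z <- compute_texture_family("glszm", disc)
  expect_equal(unname(z["glszm_GrayLevelNonUniformity"]), 1)  # one zone
  # 2-level checkerboard: GLCM contrast vs brute-force pair enumeration
  d <- array(0L, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    d[i, j, k] <- 1L + (i + j + k) %% 2L
  got <- compute_texture_family("glcm", d)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  contrasts <- apply(dirs, 1, function(dd) {
    tot <- 0; diffsum <- 0
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      ii <- i + dd[1]; jj <- j + dd[2]; kk <- k + dd[3]
      if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 4 && kk >= 1 && kk <= 4) {
        tot <- tot + 2
        diffsum <- diffsum + 2 * (d[i, j, k] - d[ii, jj, kk])^2
      }
    }
    diffsum / tot
  })
  expect_equal(unname(got["glcm_Contrast"]), mean(contrasts), tolerance = 1e-12)
  sizes <- c(glcm = 22L, glrlm = 16L, glszm = 16L, gldm = 14L, ngtdm = 5L)
  for (fam in names(sizes))
    expect_length(compute_texture_family(fam, d), sizes[[fam]])
  expect_error(compute_texture_family("bogus", d))
})

test_that("texture features are invariant to adding a constant", {
  set.seed(3)
  vals <- array(runif(6^3), c(6, 6, 6))
  mask <- array(runif(6^3) < 0.8, c(6, 6, 6))
  mk_disc <- function(v) {
    d <- array(0L, dim(mask)); d[mask] <- discretize_intensities(v[mask]); d
  }
  for (fam in c("glcm", "glrlm", "glszm", "gldm", "ngtdm")) {
    a <- compute_texture_family(fam, mk_disc(vals))
    b <- compute_texture_family(fam, mk_disc(vals + 17.3))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("first-order and GLCM match the independent frozen oracle", {
  exp_tab <- read.csv(test_path("fixtures", "oracle_firstorder_glcm.csv"),
                      check.names = FALSE)
  for (id in exp_tab$parcel) {
    p <- oracle_parcel(id)
    vals <- p$values[p$mask]
    fo <- compute_first_order(vals)
    disc <- array(0L, dim(p$mask))
    disc[p$mask] <- discretize_intensities(vals)
    gl <- compute_texture_family("glcm", disc)
    got <- c(fo, gl)
    e <- unlist(exp_tab[exp_tab$parcel == id, -1])
    rel <- abs(got[names(e)] - e) / pmax(abs(e), 1e-10)
    expect_lt(max(rel), 1e-4)
  }
})
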