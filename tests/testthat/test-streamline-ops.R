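# Streamline geometry: resampling, MDF, orientation, centerlines,
# reduction, and traversed-voxel counting.

test_that("resampling places points at equal arc length", {
  s <- streamline(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_equal(unclass(resample_streamline(s, 3)),
               rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)))
  expect_equal(unclass(resample_streamline(s, 2)), unclass(s))
  # L-shape: midpoint at arc length 10 = the corner
  L <- streamline(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0)))
  expect_equal(unclass(resample_streamline(L, 3))[2, ], c(10, 0, 0))
  expect_error(resample_streamline(s, 1), ">= 2")
})

test_that("resampling preserves endpoints and arc length", {
  # smooth space curves, the geometry streamlines actually have
  set.seed(4)
  for (rep in 1:10) {
    a <- runif(3, 0.5, 2); ph <- runif(3, 0, pi)
    t <- seq(0, 4, length.out = 30)
    pts <- cbind(10 * sin(a[1] * t + ph[1]), 10 * cos(a[2] * t + ph[2]),
                 10 * t / 4 + sin(a[3] * t + ph[3]))
    s <- streamline(pts)
    r <- resample_streamline(s, 50)
    expect_identical(unclass(r)[1, ], pts[1, ])
    expect_identical(unclass(r)[50, ], pts[30, ])
    len <- function(m) sum(sqrt(rowSums(diff(m)^2)))
    expect_lt(abs(len(unclass(r)) - len(pts)) / len(pts), 0.01)
  }
})

test_that("MDF distance handles equality, reversal, and translation", {
  set.seed(5)
  a <- streamline(apply(matrix(rnorm(24), ncol = 3), 2, cumsum))
  expect_equal(mdf_distance(a, a), list(distance = 0, flipped = FALSE))
  rev_a <- streamline(unclass(a)[nrow(a):1, ])
  r <- mdf_distance(a, rev_a)
  expect_equal(r$distance, 0, tolerance = 1e-12)
  expect_true(r$flipped)
  b <- streamline(sweep(unclass(a), 2, c(-3, 0, 0)))
  expect_equal(mdf_distance(a, b)$distance, 3, tolerance = 1e-12)
  # symmetry
  d1 <- mdf_distance(a, b)$distance
  d2 <- mdf_distance(b, a)$distance
  expect_equal(d1, d2)
})

test_that("start-ROI orientation flips reversed streamlines and is idempotent", {
  roi <- array(0, c(10, 10, 10)); roi[2, 2, 2] <- 1
  roi <- binary_mask(roi)
  ref <- ref_grid(c(10, 10, 10))
  fwd <- streamline(rbind(c(1, 1, 1), c(5, 5, 5), c(8, 8, 8)))
  bwd <- streamline(rbind(c(8, 8, 8), c(5, 5, 5), c(1, 1, 1)))
  tg <- tractogram(list(fwd, bwd), ref)
  out <- orient_by_start_roi(tg, roi)
  expect_equal(unclass(out$streamlines[[1]]), unclass(fwd))
  expect_equal(unclass(out$streamlines[[2]]), unclass(fwd))
  out2 <- orient_by_start_roi(out, roi)
  expect_equal(out2$streamlines, out$streamlines)
  # equidistant endpoints keep input order
  sym <- streamline(rbind(c(2, 1, 1), c(2, 5, 5), c(2, 1, 1) + c(0, 0, 0.001)))
  roi2 <- array(0, c(10, 10, 10)); roi2[3, 2, 2] <- 1
  tg3 <- orient_by_start_roi(tractogram(list(sym), ref), binary_mask(roi2))
  expect_equal(unclass(tg3$streamlines[[1]])[1, ], c(2, 1, 1))
  expect_error(orient_by_start_roi(tg, binary_mask(array(0, c(2, 2, 2)))),
               "empty")
})

test_that("centerline orientation aligns flipped streamlines", {
  ref <- ref_grid(c(10, 10, 10))
  base <- rbind(c(1, 1, 1), c(3, 3, 3), c(8, 8, 8))
  tg <- tractogram(list(streamline(base),
                        streamline(base[3:1, ]),
                        streamline(sweep(base, 2, c(0.5, 0, 0), "+"))), ref)
  cl <- streamline(base)
  out <- orient_by_centerline(tg, cl)
  for (s in out$streamlines) expect_false(mdf_distance(s, cl)$flipped)
  out2 <- orient_by_centerline(out, cl)
  expect_equal(out2$streamlines, out$streamlines)
})

test_that("centerline is the pointwise mean of resampled streamlines", {
  ref <- ref_grid(c(20, 20, 20))
  a <- streamline(rbind(c(4, 5, 1), c(4, 5, 18)))
  b <- streamline(rbind(c(6, 5, 1), c(6, 5, 18)))
  cl <- compute_centerline(tractogram(list(a, b), ref), 7)
  expect_equal(unclass(cl)[, 1], rep(5, 7))
  expect_equal(unclass(cl)[, 3], seq(1, 18, length.out = 7))
  one <- compute_centerline(tractogram(list(a), ref), 5)
  expect_equal(unclass(one), unclass(resample_streamline(a, 5)))
  cc <- compute_centerline(tractogram(list(a), ref), 4, positions = "centers")
  expect_equal(unclass(cc)[, 3], 1 + (17 * c(1, 3, 5, 7) / 8))
})

test_that("reduction keeps small inputs, merges groups, and is seeded", {
  ref <- ref_grid(c(100, 100, 100))
  set.seed(6)
  mk <- function(offset) {
    streamline(cbind(offset[1] + rnorm(10, sd = 0.1),
                     offset[2] + rnorm(10, sd = 0.1),
                     seq(0, 50, length.out = 10)))
  }
  small <- tractogram(replicate(40, mk(c(0, 0)), simplify = FALSE), ref)
  expect_equal(length(reduce_streamlines(small, 500)), 40L)
  # 5 well-separated groups -> 5 representatives
  offsets <- list(c(0, 0), c(60, 0), c(0, 60), c(60, 60), c(30, 90))
  sl <- unlist(lapply(offsets, function(o)
    replicate(40, mk(o), simplify = FALSE)), recursive = FALSE)
  tg <- tractogram(sl, ref)
  red <- reduce_streamlines(tg, target = 5, seed = 1)
  expect_equal(length(red), 5L)
  # each representative sits near one group center
  reps <- t(vapply(red$streamlines, function(s) colMeans(unclass(s))[1:2],
                   numeric(2)))
  d <- as.matrix(dist(rbind(reps, do.call(rbind, offsets))))[1:5, 6:10]
  expect_true(all(apply(d, 2, min) < 2))
  # identical streamlines collapse to one representative
  same <- tractogram(replicate(10, streamline(rbind(c(0, 0, 0), c(0, 0, 9))),
                               simplify = FALSE), ref)
  red1 <- reduce_streamlines(same, 1)
  expect_equal(length(red1), 1L)
  expect_equal(unclass(resample_streamline(red1$streamlines[[1]], 2)),
               rbind(c(0, 0, 0), c(0, 0, 9)), tolerance = 1e-10)
  # reproducible under a fixed seed
  r1 <- reduce_streamlines(tg, 5, seed = 3)
  r2 <- reduce_streamlines(tg, 5, seed = 3)
  expect_equal(r1$streamlines, r2$streamlines)
  expect_error(reduce_streamlines(tg, 0), ">= 1")
})

test_that("traversed-voxel count matches a fine-step rasterization oracle", {
  grid <- scalar_image(array(0, c(10, 10, 10)))
  # axial segment through 10 unit voxel centers
  s <- streamline(rbind(c(4, 4, 0), c(4, 4, 9)))
  expect_equal(count_traversed_voxels(s, grid), 10L)
  # contained in one voxel
  s1 <- streamline(rbind(c(2.1, 2.1, 2.1), c(2.3, 2.2, 2.1)))
  expect_equal(count_traversed_voxels(s1, grid), 1L)
  # entirely outside
  s2 <- streamline(rbind(c(50, 50, 50), c(60, 60, 60)))
  expect_equal(count_traversed_voxels(s2, grid), 0L)
  # diagonal + random polylines vs an independent fine-step oracle
  oracle <- function(pts, step = 0.05) {
    seg <- sqrt(rowSums(diff(pts)^2))
    dense <- list()
    for (i in seq_len(nrow(pts) - 1)) {
      k <- max(1, ceiling(seg[i] / step))
      f <- seq(0, 1, length.out = k + 1)[-(k + 1)]
      dense[[i]] <- outer(1 - f, pts[i, ]) + outer(f, pts[i + 1, ])
    }
    dense <- rbind(do.call(rbind, dense), pts[nrow(pts), , drop = FALSE])
    idx <- ceiling(dense - 0.5)        # identity affine, 0-based centers
    keep <- rowSums(idx >= 0 & idx <= 9) == 3
    nrow(unique(idx[keep, , drop = FALSE]))
  }
  diag3 <- grid <- scalar_image(array(0, c(3, 3, 3)))
  sd3 <- streamline(rbind(c(0, 0, 0), c(2, 2, 2)))
  expect_equal(count_traversed_voxels(sd3, diag3),
               oracle(rbind(c(0, 0, 0), c(2, 2, 2))))
  grid10 <- scalar_image(array(0, c(10, 10, 10)))
  set.seed(7)
  for (rep in 1:5) {
    pts <- cbind(runif(6, 0, 9), runif(6, 0, 9), runif(6, 0, 9))
    cnt <- count_traversed_voxels(streamline(pts), grid10, step = 0.05)
    expect_equal(cnt, oracle(pts))
    # reversal invariance
    expect_equal(count_traversed_voxels(streamline(pts[6:1, ]), grid10),
                 count_traversed_voxels(streamline(pts), grid10))
  }
})
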