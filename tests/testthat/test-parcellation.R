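# Voxel-space parcellation, the centerline baseline, and Dice
# evaluation.

test_that("automatic parcel count is round(mean traversed / m), clamped", {
  # streamline crossing exactly 85 unit voxels -> n = 17 at m = 5
  grid <- scalar_image(array(0, c(4, 4, 90)))
  s85 <- streamline(rbind(c(1, 1, 0), c(1, 1, 84)))
  tg <- tractogram(list(s85), ref_grid(c(4, 4, 90)))
  expect_equal(count_traversed_voxels(s85, grid), 85L)
  expect_equal(estimate_num_parcels(tg, grid, m = 5), 17L)
  s10 <- streamline(rbind(c(1, 1, 0), c(1, 1, 9)))
  tg10 <- tractogram(list(s10), ref_grid(c(4, 4, 90)))
  expect_equal(estimate_num_parcels(tg10, grid, m = 5), 2L)
  s2 <- streamline(rbind(c(1, 1, 0), c(1, 1, 1)))
  tg2 <- tractogram(list(s2), ref_grid(c(4, 4, 90)))
  expect_equal(estimate_num_parcels(tg2, grid, m = 5), 1L)   # clamp
  out <- tractogram(list(streamline(rbind(c(200, 200, 200), c(201, 201, 201)))),
                    ref_grid(c(4, 4, 90)))
  expect_error(estimate_num_parcels(out, grid), "overlaps")
})

test_that("n = 1 gives a constant model labelling everything 1", {
  tg <- tractogram(list(streamline(rbind(c(0, 0, 0), c(0, 0, 9)))),
                   ref_grid(c(5, 5, 10)))
  mod <- fit_parcellation_model(tg, 1)
  expect_equal(predict(mod, rbind(c(0, 0, 0), c(100, -3, 2))), c(1L, 1L))
  m <- array(1, c(2, 2, 2))
  lab <- parcellate_voxels(mod, binary_mask(m))
  expect_true(all(lab$data == 1))
})

test_that("tube phantom: the model reproduces its training labels", {
  tws <- tube_with_slabs(seed = 3, n = 5)
  tg <- orient_by_start_roi(tws$bundle$tractogram, tws$bundle$start_roi)
  mod <- fit_parcellation_model(tg, 5, seed = 1)
  fracs <- (1:5 - 0.5) / 5
  X <- do.call(rbind, lapply(tg$streamlines, function(s)
    tractomics:::.arc_resample(unclass(s), fracs)))
  y <- rep(1:5, times = length(tg$streamlines))
  acc <- mean(predict(mod, X) == y)
  expect_gte(acc, 0.9)
})

test_that("parcellation is invariant to pre-flip + start-ROI realignment", {
  tws <- tube_with_slabs(seed = 9, n = 4)
  b <- tws$bundle
  tg <- orient_by_start_roi(b$tractogram, b$start_roi)
  flipped <- b$tractogram
  flipped$streamlines <- lapply(flipped$streamlines, function(s)
    streamline(unclass(s)[nrow(s):1, ]))
  tg2 <- orient_by_start_roi(flipped, b$start_roi)
  m1 <- fit_parcellation_model(tg, 4, seed = 1)
  m2 <- fit_parcellation_model(tg2, 4, seed = 1)
  probe <- voxel_centers(b$envelope)
  expect_equal(predict(m1, probe), predict(m2, probe))
})

test_that("voxel parcellation partitions the mask", {
  tws <- tube_with_slabs(seed = 3, n = 5)
  b <- tws$bundle
  tg <- orient_by_start_roi(b$tractogram, b$start_roi)
  mod <- fit_parcellation_model(tg, 5, seed = 1)
  lab <- parcellate_voxels(mod, b$envelope)
  expect_true(all(lab$data[b$envelope$data > 0] %in% 1:5))
  expect_true(all(lab$data[b$envelope$data == 0] == 0))
  expect_equal(sum(tabulate(lab$data[lab$data > 0], 5)), sum(b$envelope$data))
  expect_error(parcellate_voxels(mod, binary_mask(array(0, c(2, 2, 2)))),
               "empty")
})

test_that("centerline parcellation labels by nearest centerline point", {
  m <- array(1, c(5, 5, 5))
  mask <- binary_mask(m)
  cl <- rbind(c(2, 2, 0), c(2, 2, 2), c(2, 2, 4))
  lab <- centerline_parcellation(cl, mask)
  expect_equal(lab$data[3, 3, 1], 1)     # voxel at centerline point 1
  expect_equal(lab$data[3, 3, 3], 2)
  expect_equal(lab$data[3, 3, 5], 3)
  expect_true(all(lab$data %in% 1:3))
})

test_that("predicted labels are monotone along training streamlines", {
  tws <- tube_with_slabs(seed = 3, n = 5)
  tg <- orient_by_start_roi(tws$bundle$tractogram, tws$bundle$start_roi)
  mod <- fit_parcellation_model(tg, 5, seed = 1)
  med3 <- function(x) {
    n <- length(x)
    vapply(seq_len(n), function(i)
      median(x[max(1, i - 1):min(n, i + 1)]), numeric(1))
  }
  for (s in tg$streamlines[seq(1, 200, by = 20)]) {
    walk <- unclass(resample_streamline(s, 40))
    lab <- med3(predict(mod, walk))
    expect_true(all(diff(lab) >= 0))
  }
})

test_that("streamline-density changes barely move the parcellation", {
  # doubling the dense core before reduction changes < 5% of voxels
  tws <- tube_with_slabs(seed = 12, n = 5)
  b <- tws$bundle
  tg <- orient_by_start_roi(b$tractogram, b$start_roi)
  core <- Filter(function(s) {
    mean(sqrt(rowSums(sweep(unclass(s)[, 1:2], 2, c(12, 12))^2))) < 1
  }, tg$streamlines)
  dense <- tg
  dense$streamlines <- c(tg$streamlines, core, core)
  m1 <- fit_parcellation_model(tg, 5, seed = 1, reduce_target = 100)
  m2 <- fit_parcellation_model(dense, 5, seed = 1, reduce_target = 100)
  l1 <- parcellate_voxels(m1, b$envelope)
  l2 <- parcellate_voxels(m2, b$envelope)
  sel <- b$envelope$data > 0
  expect_lt(mean(l1$data[sel] != l2$data[sel]), 0.05)
})

test_that("parcel-wise Dice handles identity, disjoint, and partial overlap", {
  a <- array(0L, c(4, 4, 4)); a[1:2, , 1] <- 1L; a[3:4, , 1] <- 2L
  ia <- label_image(a, n_parcels = 2)
  expect_equal(parcelwise_dice(ia, ia), c(1, 1))
  b <- array(0L, c(4, 4, 4)); b[1:2, , 2] <- 1L; b[3:4, , 1] <- 2L
  ib <- label_image(b, n_parcels = 2)
  expect_equal(parcelwise_dice(ia, ib)[1], 0)
  # |A|=4, |B|=4, overlap 2 -> 0.5
  a2 <- array(0L, c(4, 4, 4)); a2[1:4, 1, 1] <- 1L
  b2 <- array(0L, c(4, 4, 4)); b2[3:4, 1, 1] <- 1L; b2[1:2, 2, 1] <- 1L
  expect_equal(parcelwise_dice(label_image(a2, n_parcels = 1),
                               label_image(b2, n_parcels = 1)), 0.5)
  # both empty -> 1
  e <- label_image(array(0L, c(4, 4, 4)), n_parcels = 1)
  expect_equal(parcelwise_dice(e, e), 1)
  expect_error(parcelwise_dice(ia, label_image(a, n_parcels = 3)), "parcel")
})
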