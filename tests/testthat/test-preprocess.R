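test_that("HU windowing clips and rescales exactly", {
  v <- array(c(-2000, -1000, -300, 400, 1000, 0), c(6, 1, 1))
  w <- window_and_normalize(v)
  expect_equal(as.vector(w)[1:4], c(0, 0, 0.5, 1))
  expect_equal(as.vector(w)[5], 1)              # clipped ceiling
  expect_equal(as.vector(w)[6], 1000 / 1400)
  expect_error(window_and_normalize(array(NaN, c(1, 1, 1))), "finite")
  expect_error(window_and_normalize(v, lo_hu = 0, hi_hu = 0), "hi_hu")
})

test_that("resampling preserves constants and doubles shapes from 2 mm", {
  vol <- ct_volume(array(-500, c(16, 16, 16)), spacing_mm = c(2, 2, 2))
  out <- resample_to_isotropic(vol)
  expect_equal(dim(out$voxels), c(32L, 32L, 32L))
  expect_equal(out$spacing_mm, c(1, 1, 1))
  expect_true(all(out$voxels == -500))
})

test_that("resampling reproduces a linear HU ramp at the new coordinates", {
  # value at input index i is f(i * s) with f affine; trilinear interpolation
  # is exact for affine fields away from the clamped boundary
  nx <- 32
  f <- function(x_mm) -900 + 7 * x_mm
  v <- array(rep(f((0:(nx - 1)) * 2), times = 8 * 8), c(nx, 8, 8))
  out <- resample_to_isotropic(ct_volume(v, spacing_mm = c(2, 3, 3)))
  expect_equal(dim(out$voxels)[1], 64L)
  interior <- 1:62  # last output plane maps beyond the input extent (clamped)
  expect_equal(out$voxels[interior, 1, 1], f((interior - 1) * 1),
               tolerance = 1e-4)
})

test_that("lesion-centred crops are centred, scaled and zero-padded", {
  v <- array(0.25, c(64, 64, 64))
  # centred box
  res <- crop_centered_roi(v, bbox3d(c(32, 32, 32), c(8, 8, 8), "voxel"),
                           c(32, 32, 32))
  expect_equal(res$bbox$center, c(0.5, 0.5, 0.5))
  expect_equal(res$bbox$size, c(0.25, 0.25, 0.25))
  expect_equal(dim(res$grid), c(32L, 32L, 32L))

  # center 4 voxels from the x = 0 face: 12 padded planes, centring exact
  res2 <- crop_centered_roi(v, bbox3d(c(4, 32, 32), c(6, 6, 6), "voxel"),
                            c(32, 32, 32))
  expect_true(all(res2$grid[1:12, , ] == 0))
  expect_true(all(res2$grid[13:32, , ] == 0.25))
  expect_equal(res2$bbox$center[1], 0.5)

  expect_error(crop_centered_roi(v, bbox3d(c(200, 32, 32), c(4, 4, 4),
                                           "voxel"), c(32, 32, 32)),
               "outside")
  expect_error(crop_centered_roi(v, bbox3d(c(32, 32, 32), c(4, 4, 4),
                                           "voxel"), c(300, 300, 300)),
               "4x")
})

test_that("relative boxes round-trip to voxel coordinates within 0.5 voxel", {
  set.seed(3)
  v <- array(runif(40^3), c(40, 40, 40))
  for (i in 1:20) {
    ctr <- runif(3, 10, 30)
    sz <- runif(3, 2, 8)
    bb <- bbox3d(ctr, sz, "voxel")
    res <- crop_centered_roi(v, bb, c(24, 24, 24))
    back <- bbox_to_voxel(res$bbox, res$origin, c(24, 24, 24))
    expect_true(all(abs(back$center - ctr) <= 0.5))
    expect_true(all(abs(back$size - sz) <= 0.5))
  }
})

test_that("flips mirror the grid, reflect the box center and are involutions", {
  set.seed(4)
  g <- array(runif(16 * 16 * 16), c(16, 16, 16))
  bb <- bbox3d(c(0.3, 0.6, 0.45), c(0.2, 0.2, 0.2), "relative")
  f <- flip_with_bbox(g, bb, 0)
  expect_equal(f$bbox$center, c(0.7, 0.6, 0.45))
  expect_equal(f$bbox$size, bb$size)
  ff <- flip_with_bbox(f$grid, f$bbox, 0)
  expect_identical(ff$grid, g)
  expect_equal(ff$bbox$center, bb$center)
  expect_error(flip_with_bbox(g, bb, 3), "axis")

  # the intensity argmax mirrors exactly together with the box center
  for (ax in 0:2) {
    pos <- which(g == max(g), arr.ind = TRUE)[1, ]
    fl <- flip_with_bbox(g, bb, ax)
    pos_f <- which(fl$grid == max(fl$grid), arr.ind = TRUE)[1, ]
    expected <- pos
    expected[ax + 1] <- dim(g)[ax + 1] + 1 - pos[ax + 1]
    expect_equal(unname(pos_f), unname(expected))
  }
})

test_that("the composed pipeline yields exact shapes and [0,1] intensities", {
  spec <- tiny_spec(noise_sd = 0.05, spacing = c(0.8, 0.8, 1.25),
                    shape = c(72L, 72L, 48L))
  cs <- sample_case(spec, 2L, seed = 8)
  pp <- preprocess_case(cs$volume, cs$bbox, crop_small = c(32, 32, 32),
                        crop_large = c(64, 64, 32))
  expect_equal(dim(pp$roi_small), c(32L, 32L, 32L))
  expect_equal(dim(pp$roi_large), c(64L, 64L, 32L))
  expect_true(all(pp$roi_small >= 0 & pp$roi_small <= 1))
  expect_true(all(pp$roi_large >= 0 & pp$roi_large <= 1))
  expect_true(all(c(pp$bbox_small$center, pp$bbox_small$size,
                    pp$bbox_large$center, pp$bbox_large$size) >= 0))
})

test_that("preprocessed samples cache round-trips through disk", {
  spec <- tiny_spec()
  cases <- build_dataset_memory(spec, 3, seed = 2)
  samples <- preprocess_cases(cases, crop_small = c(16, 16, 16),
                              crop_large = c(32, 32, 16))
  dir <- file.path(tempdir(), "cache")
  cache_preprocessed(samples, dir)
  back <- load_preprocessed(dir)
  expect_length(back, 3)
  expect_equal(back[[1]]$roi_small, samples[[1]]$roi_small, tolerance = 1e-6)
  expect_equal(back[[2]]$bbox_large$center, samples[[2]]$bbox_large$center,
               tolerance = 1e-7)
  expect_equal(back[[3]]$label, samples[[3]]$label)
})
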