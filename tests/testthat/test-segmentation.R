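# organ_segmentation: enhancement steps, hysteresis, invariants.

test_that("constant volume: subtract mode yields 0, background mode yields c", {
  arr <- array(500, c(8, 16, 16))
  v <- make_volume(arr, spacing = c(2, 1.5, 1.5))
  enh <- enhance_nuclear_channel(v, segmentation_params())
  expect_true(all(abs(enh) < 1e-9))
  enh_bg <- enhance_nuclear_channel(v, segmentation_params(
    rolling_ball_mode = "background"))
  expect_true(all(abs(enh_bg - 500) < 1e-9))
})

test_that("a single bright voxel is suppressed by a 3x3x3 median", {
  arr <- array(0, c(9, 9, 9))
  arr[5, 5, 5] <- 1000
  # spacing chosen so the default physical kernel converts to 3x3x3 voxels
  v <- make_volume(arr, spacing = c(2.15, 1.1, 1.1))
  kv <- um_to_odd_voxels(c(4.3, 3.3, 3.3), c(2.15, 1.1, 1.1))
  expect_equal(kv, c(3L, 3L, 3L))
  med <- array(getFromNamespace("cpp_median3d", "gubquant")(
    as.numeric(arr), dim(arr), (kv - 1L) %/% 2L), dim(arr))
  expect_equal(med[5, 5, 5], 0)   # median of 27 voxels, 26 of them zero
  expect_true(all(med == 0))
})

test_that("median filter equals an R median oracle on random volumes", {
  set.seed(9)
  arr <- array(rnorm(6 * 7 * 5), c(6, 7, 5))
  med <- array(getFromNamespace("cpp_median3d", "gubquant")(
    as.numeric(arr), dim(arr), c(1L, 1L, 1L)), dim(arr))
  oracle <- arr
  for (z in 1:6) for (y in 1:7) for (x in 1:5) {
    zz <- max(1, z - 1):min(6, z + 1)
    yy <- max(1, y - 1):min(7, y + 1)
    xx <- max(1, x - 1):min(5, x + 1)
    oracle[z, y, x] <- stats::median(arr[zz, yy, xx])
  }
  expect_equal(med, oracle, tolerance = 1e-12)
})

test_that("sub-voxel median kernel is skipped with a warning", {
  arr <- array(rnorm(4 * 5 * 5, 100), c(4, 5, 5))
  v <- make_volume(arr, spacing = c(10, 10, 10))
  p <- segmentation_params(median_kernel_um = c(4.3, 3.3, 3.3))
  expect_warning(enh <- enhance_nuclear_channel(v, p), "below one voxel")
  expect_equal(dim(enh), dim(arr))
})

test_that("two nuclei 10 um apart merge into one component after closing", {
  nz <- 16; ny <- 48; nx <- 48
  arr <- array(0, c(nz, ny, nx))
  spacing <- c(2, 1, 1)
  paint_sphere <- function(arr, ctr, r = 3.5) {
    zc <- (seq_len(nz) - 0.5) * spacing[1]
    yc <- (seq_len(ny) - 0.5) * spacing[2]
    xc <- (seq_len(nx) - 0.5) * spacing[3]
    d2 <- outer(outer((zc - ctr[1])^2, (yc - ctr[2])^2, "+"), (xc - ctr[3])^2, "+")
    arr[d2 <= r^2] <- 1000
    arr
  }
  arr <- paint_sphere(arr, c(16, 19, 24))
  arr <- paint_sphere(arr, c(16, 29, 24))   # 10 um apart in y
  v <- make_volume(arr, spacing)
  # before closing: two components at a bright threshold
  expect_equal(n_components(arr > 500), 2)
  mask <- segment_organ(v, segmentation_params(low = 400, high = 600))
  expect_equal(n_components(mask$mask), 1)
  # both nucleus centres covered (the median filter may shave sphere edges)
  expect_true(mask$mask[8, 19, 24])
  expect_true(mask$mask[8, 29, 24])
  expect_gt(mean(mask$mask[arr > 500]), 0.8)
})

test_that("all-zero volume segments to an empty mask with a warning", {
  v <- make_volume(array(0, c(6, 10, 10)))
  expect_warning(mask <- segment_organ(v), "empty mask")
  expect_false(any(mask$mask))
})

test_that("no voxel reaching an explicit high threshold warns, not errors", {
  v <- make_volume(array(rnorm(6 * 10 * 10, 10, 1), c(6, 10, 10)))
  expect_warning(mask <- segment_organ(v, segmentation_params(low = 1e5, high = 1e6)),
                 "high threshold")
  expect_false(any(mask$mask))
})

test_that("uniform bright ellipsoid is recovered within one structuring element", {
  fx <- ellipsoid_volume()
  v <- make_volume(fx$arr, fx$spacing)
  mask <- segment_organ(v, segmentation_params(low = 400, high = 600))
  se <- um_to_voxels(rep(20, 3), fx$spacing)
  morph <- function(m, dilate) array(
    getFromNamespace("cpp_morph_ellipsoid", "gubquant")(
      as.numeric(m), dim(m), as.numeric(se), dilate) > 0.5, dim(m))
  expect_true(all(mask$mask[morph(fx$inside * 1, FALSE) > 0]))  # contains erosion
  expect_true(all(morph(fx$inside * 1, TRUE)[mask$mask]))       # within dilation
  expect_gt(dice_coefficient(mask$mask, fx$inside), 0.9)
})

test_that("mask monotonicity: lowering the low threshold never removes voxels", {
  ph <- generate_confocal_volume(small_phantom_spec(seed = 5))
  enh <- enhance_nuclear_channel(ph$volume)
  hi <- otsu_threshold(enh)
  hys <- function(lo) array(getFromNamespace("cpp_hysteresis3d", "gubquant")(
    as.numeric(enh), dim(enh), lo, hi), dim(enh))
  prev <- hys(0.9 * hi)
  for (f in c(0.7, 0.5, 0.3, 0.1)) {
    cur <- hys(f * hi)
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("exclusion dominance: no masked voxel inside the exclusion region", {
  ph <- generate_confocal_volume(small_phantom_spec(seed = 6))
  excl <- array(FALSE, dim(ph$organ_mask$mask))
  excl[, 1:24, ] <- TRUE
  mask <- segment_organ(ph$volume, exclusion_mask = excl)
  expect_false(any(mask$mask & excl))
  expect_true(any(mask$mask))
  expect_error(segment_organ(ph$volume, exclusion_mask = array(FALSE, c(2, 2, 2))),
               "shape")
})

test_that("closing is idempotent on piecewise-constant phantoms", {
  fx <- ellipsoid_volume(value = 800)
  se <- c(4, 6, 6)
  mo <- function(m, dilate) getFromNamespace("cpp_morph_ellipsoid", "gubquant")(
    as.numeric(m), dim(fx$arr), as.numeric(se), dilate)
  close1 <- mo(mo(fx$arr, TRUE), FALSE)
  close2 <- mo(mo(close1, TRUE), FALSE)
  expect_equal(close1, close2, tolerance = 1e-12)
})

test_that("phantom segmentation recovers the ground truth well at default noise", {
  # mid-size phantom: big enough for the default 20 um closing element not
  # to round the organ over, small enough to render in ~1 s
  ph <- generate_confocal_volume(volume_phantom_spec(
    shape = c(z = 40, y = 80, x = 80),
    spacing_um = c(z = 2.15, y = 1.1, x = 1.1),
    organ_semiaxes_um = c(z = 30, y = 24, x = 24),
    cord_length_um = 10, cord_radius_um = 5, seed = 2))
  mask <- segment_organ(ph$volume)
  expect_gt(dice_coefficient(mask$mask, ph$organ_mask$mask), 0.9)
  expect_true(is.numeric(mask$params$high))
  expect_equal(mask$params$low, 0.5 * mask$params$high)
})

test_that("segmentation params validate threshold ordering and positivity", {
  expect_error(segmentation_params(low = 10, high = 5), "must be <=")
  expect_error(segmentation_params(rolling_ball_um = -1), "positive")
  expect_error(segmentation_params(closing_um = 0), "positive")
})
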