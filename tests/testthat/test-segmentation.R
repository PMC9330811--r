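# A soft-tissue block with an embedded cube of in-window voxels: the
# simplest geometry with a known threshold answer.
block_with_cube <- function(cube_hu = -350, n_cube = 10L) {
  arr <- array(40, c(32, 32, 32))
  arr[9:(8 + n_cube), 9:(8 + n_cube), 9:(8 + n_cube)] <- cube_hu
  ct_volume(arr, 0.05, units = "HU")
}

test_that("threshold volume is count times voxel volume on a known cube", {
  v <- block_with_cube()  # 1000 voxels at -350 HU
  m <- threshold_segment(v)
  expect_equal(mask_volume_mm3(m), 1000 * 0.05^3, tolerance = 1e-12)
})

test_that("pure air at -1000 HU is excluded by the -700 floor", {
  v <- block_with_cube(cube_hu = -1000)
  expect_error(threshold_segment(v), "no voxels in window")
  # window edges are inclusive
  expect_equal(mask_volume_mm3(threshold_segment(block_with_cube(-700))),
               0.125, tolerance = 1e-12)
  expect_equal(mask_volume_mm3(threshold_segment(block_with_cube(-300))),
               0.125, tolerance = 1e-12)
})

test_that("border-touching components and sub-threshold specks are removed", {
  arr <- array(40, c(32, 32, 32))
  arr[1:5, 1:5, 1:5] <- -400      # touches the border: exterior air analogue
  arr[15:17, 15:17, 15:17] <- -400  # 27 voxels: kept (>= minimum size)
  arr[25, 25, 25] <- -400         # single-voxel speck: dropped
  m <- threshold_segment(ct_volume(arr, 0.05, units = "HU"))
  expect_identical(sum(m$data), 27L)
  expect_identical(m$data[25, 25, 25], 0L)
  expect_identical(m$data[1, 1, 1], 0L)
})

test_that("threshold requires HU units and respects a thorax restriction", {
  raw <- ct_volume(array(100, c(8, 8, 8)), 0.05)
  expect_error(threshold_segment(raw), "HU")
  v <- block_with_cube()
  restrict <- voi_mask(array(0L, dim(v$data)), v$spacing)
  restrict$data[9:13, , ] <- 1L   # keep only 5 of the 10 cube slices
  m <- threshold_segment(v, thorax_restrict = restrict)
  expect_identical(sum(m$data), 500L)
})

test_that("widening the window never shrinks the mask (phantom subset test)", {
  ph <- generate_thorax_phantom(small_spec(noise_sd = 15, seed = 9))
  m_narrow <- threshold_segment(ph$volume, hu_window_alternate())
  m_wide <- threshold_segment(ph$volume, hu_window_reference())
  expect_identical(sum(m_narrow$data == 1L & m_wide$data == 0L), 0L)
  expect_lt(sum(m_narrow$data), sum(m_wide$data))
})

test_that("zero-noise phantom threshold recovers the aerated truth", {
  ph <- generate_thorax_phantom(small_spec())
  v <- mask_volume_mm3(threshold_segment(ph$volume))
  expect_lt(abs(v - ph$truth$aerated_mm3) / ph$truth$aerated_mm3, 0.02)
})

test_that("on a pathologic phantom the window misses lesions that contours include", {
  ph <- generate_thorax_phantom(
    small_spec(pathology = "consolidation", burden = 0.25))
  thr <- mask_volume_mm3(threshold_segment(ph$volume))
  expect_lt(thr, ph$truth$lung_mm3)  # threshold < delineated total lung
})

test_that("fully annotated contours reduce to exact per-slice rasterisation", {
  grid <- ct_volume(array(0, c(40, 64, 64)), 0.1, units = "HU")
  sc <- circle_contours(grid, r = 1.5, slices = 5:35)
  m <- delineate_from_contours(sc, grid)
  # no mask outside the annotated extent
  expect_identical(sum(m$data[c(1:4, 36:40), , ]), 0L)
  # every annotated slice is a disc of the analytic area (to rasterisation)
  a_mid <- sum(m$data[20, , ]) * 0.1^2
  expect_lt(abs(a_mid - pi * 1.5^2) / (pi * 1.5^2), 0.05)
})

test_that("sphere annotated on every 2nd slice interpolates to the analytic volume", {
  grid <- ct_volume(array(0, c(96, 96, 96)), 0.05, units = "HU")
  sc <- circle_contours(grid, r = 2, slices = seq(1, 96, by = 2))
  m <- delineate_from_contours(sc, grid)
  target <- 4 / 3 * pi * 2^3
  expect_lt(abs(mask_volume_mm3(m) - target) / target, 0.02)
})

test_that("volume is stable under annotation refinement on a convex body", {
  grid <- ct_volume(array(0, c(96, 96, 96)), 0.05, units = "HU")
  coarse <- delineate_from_contours(
    circle_contours(grid, 2, seq(1, 96, by = 2)), grid)
  fine <- delineate_from_contours(
    circle_contours(grid, 2, seq(1, 96, by = 1)), grid)
  expect_lt(abs(mask_volume_mm3(coarse) - mask_volume_mm3(fine)) /
              mask_volume_mm3(fine), 0.01)
})

test_that("contour contracts: slice count, bounds, self-intersection", {
  grid <- ct_volume(array(0, c(20, 20, 20)), 0.1, units = "HU")
  sq <- cbind(c(0.5, 0.5, 1.2, 1.2), c(0.5, 1.2, 1.2, 0.5))
  expect_error(slice_contours(list(`5` = sq)), "2 annotated")
  big <- sq + 5  # beyond the 1.9 mm extent
  expect_error(delineate_from_contours(
    slice_contours(list(`5` = big, `10` = big)), grid), "out of bounds")
  bow <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))  # figure-eight
  expect_error(slice_contours(list(`5` = bow, `9` = bow)),
               "self-intersecting")
})

test_that("contours survive a JSON round trip", {
  sq <- cbind(c(0.5, 0.5, 1.2, 1.2), c(0.5, 1.2, 1.2, 0.5))
  sc <- slice_contours(list(`3` = sq, `7` = sq * 0.9))
  f <- tempfile(fileext = ".json")
  write_contours(sc, f)
  r <- read_contours(f)
  expect_equal(r$index, sc$index)
  expect_equal(r$slices[["3"]][[1]], sc$slices[["3"]][[1]])
})

test_that("mask volumetry zero and arithmetic cases", {
  expect_identical(mask_volume_mm3(voi_mask(array(0L, c(4, 4, 4)), 0.05)), 0)
  m <- voi_mask(array(1L, c(20, 20, 20)), 0.05)
  expect_equal(mask_volume_mm3(m), 1.0, tolerance = 1e-12)  # 8000 voxels
})
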