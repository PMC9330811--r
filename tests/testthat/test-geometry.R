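lm_box <- function(d_small = 4, d_large = 8, height = 10) {
  landmark_set(
    small_base = rbind(c(0, 5, 5 - d_small / 2), c(0, 5, 5 + d_small / 2)),
    large_base = rbind(c(height, 5 - d_large / 2, 5),
                       c(height, 5 + d_large / 2, 5)),
    height = rbind(c(0, 5, 5), c(height, 5, 5)))
}

test_that("landmark distances are Euclidean in mm", {
  lm <- landmark_set(
    small_base = rbind(c(0, 0, 0), c(0, 0, 7.5)),     # axis-aligned
    large_base = rbind(c(0, 3, 4), c(0, 0, 0)),       # 3-4-5 triangle
    height = rbind(c(1, 1, 1), c(4, 5, 13)))
  m <- measure_thorax(lm)
  expect_equal(m$d_small, 7.5, tolerance = 1e-12)
  expect_equal(m$d_large, 5.0, tolerance = 1e-12)
  expect_equal(m$height, 13, tolerance = 1e-12)
  expect_error(landmark_set(rbind(c(1, 1, 1), c(1, 1, 1)),
                            lm$large_base, lm$height), "coincident")
})

test_that("frustum volume matches closed-form limit cases", {
  # cylinder: equal bases, r = 1, h = 3
  expect_equal(truncated_cone_volume(measure_thorax(lm_box(2, 2, 3))),
               pi * 3, tolerance = 1e-9)
  # full cone limit: tiny top, d_large = 8, h = 10 -> (pi*10/3)*16
  v_cone <- truncated_cone_volume(
    data.frame(d_small = 1e-9, d_large = 8, height = 10))
  expect_equal(v_cone, pi * 10 / 3 * 16, tolerance = 1e-6)
  # generic frustum: R1 = 2, R2 = 4, h = 10
  expect_equal(truncated_cone_volume(measure_thorax(lm_box(4, 8, 10))),
               pi * 10 / 3 * (4 + 16 + 8), tolerance = 1e-9)
})

test_that("frustum volume is symmetric in its bases and monotone in all arguments", {
  v0 <- truncated_cone_volume(data.frame(d_small = 4, d_large = 8, height = 10))
  expect_equal(truncated_cone_volume(
    data.frame(d_small = 8, d_large = 4, height = 10)), v0, tolerance = 1e-12)
  for (col in c("d_small", "d_large", "height")) {
    df <- data.frame(d_small = 4, d_large = 8, height = 10)
    df[[col]] <- df[[col]] * 1.1
    expect_gt(truncated_cone_volume(df), v0)
  }
})

test_that("halving convention doubles radii when disabled", {
  m <- data.frame(d_small = 4, d_large = 8, height = 10)
  expect_equal(truncated_cone_volume(m, halve_diameters = FALSE),
               4 * truncated_cone_volume(m), tolerance = 1e-12)
})

test_that("analytic frustum agrees with a voxelisation oracle within 1%", {
  set.seed(31)
  for (i in 1:8) {
    d1 <- runif(1, 5, 9); d2 <- runif(1, 8, 13); h <- runif(1, 8, 14)
    analytic <- truncated_cone_volume(
      data.frame(d_small = d1, d_large = d2, height = h))
    voxel <- voxelized_frustum_mm3(d1, d2, h, sp = 0.05)
    expect_lt(abs(analytic - voxel) / analytic, 0.01)
  }
})

test_that("phantom landmark manifest reproduces the spec geometry", {
  s <- small_spec()
  ph <- generate_thorax_phantom(s)
  m <- measure_thorax(ph$truth$landmarks)
  expect_equal(m$d_small, s$carina_width, tolerance = s$spacing[1])
  expect_equal(m$d_large, s$diaphragm_depth, tolerance = s$spacing[1])
  expect_equal(m$height, s$height, tolerance = s$spacing[1])
  # rib-to-rib fallback is slightly wider than the lung-limit small base
  m_ribs <- measure_thorax(ph$truth$landmarks_ribs)
  expect_gt(m_ribs$d_small, m$d_small)
  expect_equal(m_ribs$d_small, m$d_small + 0.3, tolerance = 1e-9)
})

test_that("image-level measurement checks bounds and is rotation invariant", {
  ph <- generate_thorax_phantom(small_spec())
  res <- thoracic_volume_from_image(ph$volume, ph$truth$landmarks)
  expect_equal(res$volume_mm3,
               truncated_cone_volume(res$measure), tolerance = 1e-12)
  # landmarks outside the grid extent are rejected
  out_lm <- landmark_set(rbind(c(0, 0, 0), c(0, 0, 99)),
                         ph$truth$landmarks$large_base,
                         ph$truth$landmarks$height)
  expect_error(thoracic_volume_from_image(ph$volume, out_lm), "outside")
  # rotating all landmark pairs rigidly leaves the volume unchanged
  R <- rotation_matrix(yaw = 23, pitch = 11, roll = 7)
  rot <- function(p) t(R %*% t(p))
  lm <- ph$truth$landmarks
  lm_rot <- landmark_set(rot(lm$small_base), rot(lm$large_base),
                         rot(lm$height))
  expect_equal(truncated_cone_volume(measure_thorax(lm_rot)),
               res$volume_mm3, tolerance = 1e-9)
})

test_that("landmark sets survive a JSON round trip", {
  lm <- lm_box()
  f <- tempfile(fileext = ".json")
  write_landmarks(lm, f)
  r <- read_landmarks(f)
  expect_equal(r$small_base, lm$small_base)
  expect_equal(r$height, lm$height)
})
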