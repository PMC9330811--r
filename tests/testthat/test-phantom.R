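test_that("same spec and seed give bit-identical phantoms", {
  s <- small_spec(noise_sd = 20)
  a <- generate_thorax_phantom(s)
  b <- generate_thorax_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$aerated_mm3, b$truth$aerated_mm3)
  d <- generate_thorax_phantom(small_spec(noise_sd = 20, seed = 43L))
  expect_false(identical(a$volume$data, d$volume$data))
})

test_that("manifest volumes equal voxel counts times voxel volume, exactly", {
  ph <- generate_thorax_phantom(small_spec())
  expect_identical(ph$truth$thoracic_mm3, mask_volume_mm3(ph$masks$cavity))
  expect_identical(ph$truth$lung_mm3, mask_volume_mm3(ph$masks$lung))
  expect_identical(ph$truth$aerated_mm3, mask_volume_mm3(ph$masks$aerated))
  expect_true(ph$truth$aerated_mm3 <= ph$truth$lung_mm3)
  expect_true(ph$truth$lung_mm3 <= ph$truth$thoracic_mm3)
})

test_that("aeration fraction 1 with no pathology makes all lung aerated", {
  ph <- generate_thorax_phantom(small_spec(aeration_fraction = 1))
  expect_identical(ph$truth$aerated_mm3, ph$truth$lung_mm3)
  expect_false(ph$truth$pathologic)
})

test_that("consolidation burden 0.3 leaves 0.7 of the lung aerated", {
  ph <- generate_thorax_phantom(
    small_spec(aeration_fraction = 1, pathology = "consolidation",
               burden = 0.3))
  vv <- voxel_volume_mm3(ph$volume)
  expect_lt(abs(ph$truth$aerated_mm3 - 0.7 * ph$truth$lung_mm3), vv + 1e-12)
  expect_true(ph$truth$pathologic)
  expect_gt(ph$truth$lesion_mm3, 0)
})

test_that("truth ratios are monotone in the spec fractions", {
  lung_lo <- generate_thorax_phantom(small_spec(lung_fraction = 0.5))$truth
  lung_hi <- generate_thorax_phantom(small_spec(lung_fraction = 0.7))$truth
  expect_lt(lung_lo$lung_mm3 / lung_lo$thoracic_mm3,
            lung_hi$lung_mm3 / lung_hi$thoracic_mm3)
  aer_lo <- generate_thorax_phantom(small_spec(aeration_fraction = 0.7))$truth
  aer_hi <- generate_thorax_phantom(small_spec(aeration_fraction = 0.95))$truth
  expect_lt(aer_lo$aerated_mm3 / aer_lo$lung_mm3,
            aer_hi$aerated_mm3 / aer_hi$lung_mm3)
})

test_that("phantom intensities follow the tissue model", {
  ph <- generate_thorax_phantom(small_spec())
  v <- ph$volume$data
  aer <- v[ph$masks$aerated$data == 1L]
  expect_true(all(aer > -700 & aer < -300))
  expect_lt(abs(mean(aer) - -500), 15)
  expect_true(all(v[ph$masks$body$data == 0L] == -1000))  # exterior air
  expect_true(any(v >= 700))   # bone present
})

test_that("infeasible geometry and burden are rejected", {
  expect_error(small_spec(height = 20), "fit")
  expect_error(small_spec(pathology = "nodules", burden = 0.5,
                          aeration_fraction = 0.4), "headroom")
  expect_error(small_spec(lung_fraction = 1.4), "\\[0, 1\\]")
})

test_that("calibration phantom: designed greys are exact at zero noise and VOIs disjoint", {
  cp <- generate_calibration_phantom(noise_sd = 0)
  air <- cp$volume$data[cp$air_voi$data == 1L]
  water <- cp$volume$data[cp$water_voi$data == 1L]
  expect_identical(unique(air), cp$air_grey)
  expect_identical(unique(water), cp$water_grey)
  expect_identical(sum(cp$air_voi$data * cp$water_voi$data), 0L)
})

test_that("noisy calibration phantom VOI means stay within 3 grey (>= 1e4 voxels)", {
  cp <- generate_calibration_phantom(noise_sd = 50, seed = 11)
  expect_gte(sum(cp$air_voi$data), 1e4)
  expect_gte(sum(cp$water_voi$data), 1e4)
  expect_lt(abs(mean(cp$volume$data[cp$air_voi$data == 1L]) - cp$air_grey), 3)
  expect_lt(abs(mean(cp$volume$data[cp$water_voi$data == 1L]) - cp$water_grey), 3)
})

test_that("noiseless cohort truths recover the designed line exactly (to voxel quantisation)", {
  co <- generate_cohort(6, noise_sd = 0, seed = 2, keep_volumes = FALSE)
  fit <- fit_lung_regression(co, thoracic_mm3, lung_mm3)
  expect_equal(fit$slope, 0.20, tolerance = 1e-3)
  expect_equal(fit$intercept, 300, tolerance = 1e-2)
  expect_gt(fit$r_squared, 0.9999)
})

test_that("cohort contracts: minimum size and parameter ranges", {
  expect_error(generate_cohort(2), ">= 3")
  expect_error(generate_cohort(5, slope = 1.5), "slope")
  expect_error(generate_cohort(5, intercept = -10), "intercept")
})

test_that("cohort is reproducible under a fixed seed", {
  a <- generate_cohort(3, seed = 5, keep_volumes = FALSE)
  b <- generate_cohort(3, seed = 5, keep_volumes = FALSE)
  expect_identical(a$thoracic_mm3, b$thoracic_mm3)
  expect_identical(a$lung_mm3, b$lung_mm3)
})
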