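test_that("volume ratios follow their definitions and flag anomalies", {
  d <- tibble::tibble(thoracic_mm3 = 800, manual_mm3 = 520,
                      threshold_mm3 = 450)
  r <- volume_ratios(d)
  expect_equal(r$manual_over_thoracic_pct, 65.0, tolerance = 1e-9)
  expect_equal(r$threshold_over_manual_pct, 86.53846, tolerance = 1e-5)
  expect_equal(r$threshold_over_thoracic_pct, 56.25, tolerance = 1e-9)
  expect_false(r$anomalous)
  # manual = thoracic -> 100%
  r2 <- volume_ratios(tibble::tibble(thoracic_mm3 = 700, manual_mm3 = 700,
                                     threshold_mm3 = 600))
  expect_equal(r2$manual_over_thoracic_pct, 100)
  # aerated exceeding total lung is physically impossible: flagged, not error
  r3 <- volume_ratios(tibble::tibble(thoracic_mm3 = 800, manual_mm3 = 400,
                                     threshold_mm3 = 450))
  expect_true(r3$anomalous)
  expect_gt(r3$threshold_over_manual_pct, 100)
  expect_error(volume_ratios(tibble::tibble(thoracic_mm3 = 800,
                                            manual_mm3 = NA_real_,
                                            threshold_mm3 = 450)), "missing")
})

test_that("Bland-Altman closed form: d = {1,2,3} gives bias 2 and limits (0.04, 3.96)", {
  ba <- bland_altman(c(2, 3, 4), c(1, 1, 1))
  expect_equal(ba$bias, 2, tolerance = 1e-12)
  expect_equal(ba$sd, 1, tolerance = 1e-12)
  expect_equal(ba$loa_lower, 0.04, tolerance = 1e-9)
  expect_equal(ba$loa_upper, 3.96, tolerance = 1e-9)
  expect_equal(ba$loa_upper - ba$bias, ba$bias - ba$loa_lower,
               tolerance = 1e-9)
})

test_that("Bland-Altman of a series with itself is the zero result", {
  set.seed(2)
  a <- rnorm(25, 500, 60)
  ba <- bland_altman(a, a)
  expect_identical(ba$bias, 0)
  expect_identical(ba$loa_lower, 0)
  expect_identical(ba$loa_upper, 0)
})

test_that("swapping the series mirrors bias and limits", {
  set.seed(3)
  a <- rnorm(30, 550, 70); b <- rnorm(30, 520, 70)
  ab <- bland_altman(a, b); ba <- bland_altman(b, a)
  expect_equal(ab$bias, -ba$bias, tolerance = 1e-12)
  expect_equal(ab$loa_lower, -ba$loa_upper, tolerance = 1e-12)
  expect_equal(ab$loa_upper, -ba$loa_lower, tolerance = 1e-12)
})

test_that("simulated Normal(5, 10^2) differences recover bias and limits", {
  set.seed(41)
  d <- rnorm(1e4, 5, 10)
  ba <- bland_altman(d, rep(0, 1e4))
  expect_lt(abs(ba$bias - 5), 0.3)
  expect_lt(abs(ba$loa_lower - -14.6), 0.6)
  expect_lt(abs(ba$loa_upper - 24.6), 0.6)
  expect_error(bland_altman(1:3, 1:4), "lengths differ")
  expect_error(bland_altman(1, 1), ">= 2")
})

rr_design <- function(p = 10, o = 2, r = 3) {
  expand.grid(part = seq_len(p), operator = LETTERS[seq_len(o)],
              replicate = seq_len(r))
}

test_that("identical measurements across operators give exactly 0% operator contribution", {
  d <- rr_design()
  d$value <- 100 + 5 * d$part   # parts differ, operators/replicates identical
  g <- gage_rr(d)
  expect_equal(g$operator_pct, 0, tolerance = 1e-12)
  expect_equal(sum(g$components$pct_contribution), 100, tolerance = 1e-6)
  expect_true(all(g$components$variance >= 0))
})

test_that("Monte-Carlo Gage R&R recovers the analytic operator contribution", {
  # parts sd 50, operator sd 10, repeatability sd 5:
  # analytic contribution = 100 * 100 / (2500 + 100 + 25) = 3.81%
  est <- vapply(1:200, function(s) {
    set.seed(s)
    d <- rr_design()
    pe <- rnorm(10, 0, 50); oe <- rnorm(2, 0, 10)
    d$value <- pe[d$part] + oe[as.integer(factor(d$operator))] +
      rnorm(nrow(d), 0, 5)
    gage_rr(d)$operator_pct
  }, numeric(1))
  analytic <- 100 * 100 / (2500 + 100 + 25)
  expect_lt(abs(mean(est) - analytic), 2)
})

test_that("Gage R&R contributions are invariant to offset and positive scale", {
  set.seed(6)
  d <- rr_design()
  d$value <- rnorm(nrow(d), 100 + 4 * d$part, 3)
  g0 <- gage_rr(d)
  d_shift <- d; d_shift$value <- d_shift$value + 1234
  d_scale <- d; d_scale$value <- d_scale$value * 6.5
  expect_equal(gage_rr(d_shift)$components$pct_contribution,
               g0$components$pct_contribution, tolerance = 1e-8)
  expect_equal(gage_rr(d_scale)$components$pct_contribution,
               g0$components$pct_contribution, tolerance = 1e-8)
})

test_that("Gage R&R design contracts are enforced", {
  d1 <- rr_design(o = 1)
  d1$value <- rnorm(nrow(d1))
  expect_error(gage_rr(d1), ">= 2 operators")
  d2 <- rr_design(r = 1)
  d2$value <- rnorm(nrow(d2))
  expect_error(gage_rr(d2), ">= 2 replicates")
  d3 <- rr_design()
  d3$value <- rnorm(nrow(d3))
  expect_error(gage_rr(d3[-1, ]), "unbalanced")
})

test_that("the four deviation-rule branches classify as printed", {
  d <- tibble::tibble(scan_id = c("p_hi", "p_lo", "c_hi", "c_lo"),
                      pathologic = c(TRUE, TRUE, FALSE, FALSE),
                      volume_mm3 = c(106, 104, 106, 104))
  cl <- classify_cohort(d, reference = 100)
  expect_identical(tidy(cl)$class, c("TP", "FN", "FP", "TN"))
  expect_equal(cl$sensitivity_pct, 50)
  expect_equal(cl$specificity_pct, 50)
})

test_that("a deviation of exactly 5% is negative (strict over-5 rule)", {
  d <- tibble::tibble(scan_id = c("p", "c"), pathologic = c(TRUE, FALSE),
                      volume_mm3 = c(105, 95))
  cl <- classify_cohort(d, reference = 100)
  expect_identical(tidy(cl)$class, c("FN", "TN"))
})

test_that("sensitivity and specificity follow the confusion-matrix arithmetic", {
  # TP = 3, FN = 1, TN = 4, FP = 1 -> sensitivity 75%, specificity 80%
  d <- tibble::tibble(
    scan_id = sprintf("s%d", 1:9),
    pathologic = c(rep(TRUE, 4), rep(FALSE, 5)),
    volume_mm3 = c(110, 108, 107, 104, 106, 103, 102, 101, 100))
  cl <- classify_cohort(d, reference = 100)
  expect_equal(cl$sensitivity_pct, 75)
  expect_equal(cl$specificity_pct, 80)
})

test_that("an all-separable 7 pathologic / 2 control cohort scores 100/100", {
  d <- tibble::tibble(
    scan_id = sprintf("s%d", 1:9),
    pathologic = c(rep(TRUE, 7), FALSE, FALSE),
    volume_mm3 = c(seq(120, 180, by = 10), 99, 101))
  cl <- classify_cohort(d)  # auto reference = mean(99, 101) = 100
  expect_equal(cl$reference_mm3, 100)
  expect_equal(cl$sensitivity_pct, 100)
  expect_equal(cl$specificity_pct, 100)
})

test_that("classification is monotone in the threshold", {
  set.seed(12)
  d <- tibble::tibble(scan_id = sprintf("s%d", 1:20),
                      pathologic = rep(c(TRUE, FALSE), 10),
                      volume_mm3 = rnorm(20, 100, 8))
  pos <- function(th) sum(tidy(classify_cohort(d, reference = 100,
                                               threshold = th))$positive)
  expect_gte(pos(0.001), pos(5))
  expect_gte(pos(5), pos(50))
  expect_identical(pos(1e6), 0L)
  expect_error(classify_cohort(d[d$pathologic, ]), "no control")
})
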