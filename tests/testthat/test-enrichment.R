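test_that("calibration recovers an exact linear relation to machine precision", {
  # standards spanning the 0-2.5 MPE working range
  mpe <- c(0, 0.5, 1.0, 1.5, 2.0, 2.5)
  true_slope <- 2.0; true_intercept <- 0.05
  ratio <- (mpe - true_intercept) / true_slope
  cal <- suppressWarnings(build_calibration(data.frame(known_mpe = mpe, measured_ratio = ratio)))
  expect_equal(cal$slope, true_slope, tolerance = 1e-12)
  expect_equal(cal$intercept, true_intercept, tolerance = 1e-12)
  expect_equal(cal$valid_range, c(0, 2.5))
  expect_equal(cal$n_standards, 6L)

  ident <- suppressWarnings(build_calibration(known_mpe = c(0, 1), measured_ratio = c(0, 1)))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-14)
})

test_that("calibration rejects degenerate or decreasing standards", {
  expect_error(build_calibration(known_mpe = c(1, 1), measured_ratio = c(0.5, 0.5)),
               "degenerate")
  expect_error(build_calibration(known_mpe = c(0, 1, 2), measured_ratio = c(1, 0.5, 0)),
               "slope")
})

test_that("noisy calibration slope coverage matches the t-distribution oracle", {
  # with 6 standards and 2 coefficients the slope t-statistic has 4 df, so
  # |slope - truth| <= 3 SE should hold with probability P(|t_4| <= 3)
  mpe <- c(0, 0.5, 1.0, 1.5, 2.0, 2.5)
  true_slope <- 2.0
  expected_cover <- 1 - 2 * stats::pt(-3, df = 4)
  set.seed(2024)
  ok <- vapply(seq_len(1000), function(i) {
    ratio <- mpe / true_slope + stats::rnorm(6, 0, 0.01)
    cal <- build_calibration(known_mpe = mpe, measured_ratio = ratio)
    abs(cal$slope - true_slope) <= 3 * cal$slope_se
  }, logical(1))
  expect_lt(abs(mean(ok) - expected_cover), 0.025)
  # and the point estimate is accurate: sub-percent error in most replicates
  set.seed(2025)
  err <- vapply(seq_len(200), function(i) {
    ratio <- mpe / true_slope + stats::rnorm(6, 0, 0.01)
    abs(build_calibration(known_mpe = mpe, measured_ratio = ratio)$slope / true_slope - 1)
  }, numeric(1))
  expect_lt(median(err), 0.02)
})

test_that("ratio_to_mpe applies the line, flags extrapolation, clamps negatives", {
  ident <- suppressWarnings(build_calibration(known_mpe = c(0, 0.5, 1, 1.5, 2),
                                              measured_ratio = c(0, 0.5, 1, 1.5, 2)))
  expect_equal(ratio_to_mpe(0.8, ident)$mpe, 0.8)

  cal <- suppressWarnings(build_calibration(known_mpe = c(0.1, 0.5, 1, 1.5, 2),
                                          measured_ratio = (c(0.1, 0.5, 1, 1.5, 2) - 0.1) / 2))
  out <- ratio_to_mpe(1.0, cal)
  expect_equal(out$mpe, 2.1)
  expect_true(out$extrapolated)   # above the 2.0 MPE top standard

  # a clearly negative prediction is clamped with a warning
  steep <- suppressWarnings(build_calibration(known_mpe = c(0, 1, 2),
                                              measured_ratio = c(0.5, 1, 1.5)))
  expect_warning(neg <- ratio_to_mpe(0, steep), "clamped")
  expect_equal(neg$mpe, 0)
  expect_true(neg$clamped)
})

test_that("calibration round-trip is identity to 1e-10 within the valid range", {
  mpe <- c(0, 0.5, 1.0, 1.5, 2.0, 2.5)
  set.seed(7)
  cal <- build_calibration(known_mpe = mpe,
                           measured_ratio = mpe / 1.8 + stats::rnorm(6, 0, 0.005))
  x <- seq(0, 2.5, by = 0.1)
  back <- ratio_to_mpe(mpe_to_ratio(x, cal), cal)$mpe
  expect_equal(back, x, tolerance = 1e-10)
})

test_that("delta_to_ape follows standard isotope arithmetic", {
  expect_equal(delta_to_ape(57.3, 57.3), 0)
  expect_equal(delta_to_ape(-21.9, -21.9), 0)
  # hand-checked closed form: +100 permil vs 0 basal at VPDB ratio
  expect_equal(delta_to_ape(100, 0), 0.10922, tolerance = 1e-4)
  # strictly increasing in the sample delta at fixed basal
  d <- seq(-50, 200, by = 10)
  expect_true(all(diff(delta_to_ape(d, -10)) > 0))
  expect_error(delta_to_ape(-1000, 0), "nonphysical")
  expect_error(delta_to_ape(Inf, 0), "finite")
})

test_that("baseline correction zeroes the basal point and is idempotent", {
  cu <- enrichment_curve(study_schedule, rep(0.05, 10), animal_id = "P001",
                         analyte = "Gln-m5", unit = "MPE")
  bc <- baseline_correct(cu)
  expect_equal(bc$value, rep(0, 10))

  vals <- c(0.02, 1.20, 0.9, 0.7, 0.5, 0.4, 0.3, 0.25, 0.2, 0.1)
  cu2 <- baseline_correct(enrichment_curve(study_schedule, vals, unit = "MPE"))
  expect_equal(max(cu2$value), 1.18)
  expect_equal(cu2$value[1], 0)
  # idempotence and time-grid preservation
  cu3 <- baseline_correct(cu2)
  expect_identical(cu3$value, cu2$value)
  expect_identical(cu3$time_min, cu2$time_min)

  no_basal <- enrichment_curve(post_schedule, seq_len(9), animal_id = "P042",
                               analyte = "Glc-m6", unit = "MPE")
  expect_error(baseline_correct(no_basal), "P042")
})

test_that("negative post-correction values are retained and flagged", {
  vals <- c(0.05, 0.02, 0.5, 0.4, 0.3, 0.2, 0.15, 0.1, 0.08, 0.06)
  bc <- baseline_correct(enrichment_curve(study_schedule, vals, unit = "MPE"))
  expect_lt(bc$value[2], 0)
  expect_true(attr(bc, "negative_flags")[2])
})
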