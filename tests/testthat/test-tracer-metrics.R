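test_that("dose arithmetic matches hand calculations for the study boluses", {
  gln <- gln_tracer_dose()
  glc <- glc_tracer_dose()
  expect_equal(dose_to_mmol(gln), 0.0662, tolerance = 1e-3)
  expect_equal(dose_to_mmol(glc), 0.0537, tolerance = 1e-3)
  # excess 13C: D x n_labeled x (purity - natural abundance)
  expect_equal(tracer_excess_13c(gln), 0.3256, tolerance = 1e-3)
  expect_equal(tracer_excess_13c(glc), 0.3154, tolerance = 1e-3)
  # pure tracer with zero background: excess = D x n exactly
  pure <- tracer_dose("13C5-Gln", 10, 100, 5, 151.16, natural_abundance = 0)
  expect_equal(tracer_excess_13c(pure), dose_to_mmol(pure) * 5)
  expect_error(tracer_dose("x", 0, 99, 5, 151.16))
})

test_that("rate of appearance follows Ra = D / (AUC/100)", {
  expect_equal(rate_of_appearance(0.10, 10), 1.0)
  # printed group-mean AUC reproduces the printed Ra within the
  # ratio-of-means vs mean-of-ratios tolerance
  ra <- rate_of_appearance(dose_to_mmol(gln_tracer_dose()), 164, auc_unit = "MPE_min")
  expect_equal(ra, 2.42, tolerance = 5e-3)
  expect_lt(abs(ra / 2.68 - 1), 0.10)
  # homogeneity: proportional to D, inversely proportional to AUC
  expect_equal(rate_of_appearance(0.2, 10), 2 * rate_of_appearance(0.1, 10))
  expect_equal(rate_of_appearance(0.1, 20), rate_of_appearance(0.1, 10) / 2)
  # min- and h-scale AUC agree exactly
  expect_equal(rate_of_appearance(0.0662, 164, auc_unit = "MPE_min"),
               rate_of_appearance(0.0662, 164 / 60), tolerance = 1e-12)
  expect_error(rate_of_appearance(0.1, 0), "undefined")
})

test_that("13C recovery modes behave as documented", {
  expect_equal(as.numeric(c13_recovery(0, 0.3256)), 0)
  # hand-arithmetic example: AUC 15.4 APE x min, r 48, excess 0.3256,
  # factor 0.90, dimensional mode -> about 42.0%
  rec <- c13_recovery(15.4, 0.3256, r_co2 = 48, normalization = 0.90)
  expect_equal(as.numeric(rec), 42.0, tolerance = 0.1 / 42)
  expect_identical(attr(rec, "mode"), "dimensional")
  # the literal printed equation multiplies by the 5 h sampling period
  lit <- c13_recovery(15.4, 0.3256, normalization = 0.90, mode = "literal")
  expect_equal(as.numeric(lit), 5 * as.numeric(rec), tolerance = 1e-12)
  # linearity in the CO2 AUC, both modes
  for (m in c("dimensional", "literal")) {
    expect_equal(as.numeric(c13_recovery(30.8, 0.3256, normalization = 0.9, mode = m)),
                 2 * as.numeric(c13_recovery(15.4, 0.3256, normalization = 0.9, mode = m)))
  }
  expect_error(c13_recovery(15.4, 0.3256, normalization = 0), "normalization")
  expect_error(c13_recovery(15.4, 0), "excess")
})

test_that("gluconeogenic conversion is the AUC quotient in percent", {
  # printed group means for the low-birthweight water cell
  expect_equal(round(gluconeogenic_conversion(14.3, 138), 1), 10.4)
  expect_equal(gluconeogenic_conversion(5, 5), 100)
  expect_equal(gluconeogenic_conversion(0, 5), 0)
  # time-unit invariance as long as both AUCs share the unit
  expect_equal(gluconeogenic_conversion(14.3, 138),
               gluconeogenic_conversion(14.3 / 60, 138 / 60))
  expect_error(gluconeogenic_conversion(1, 0), "AUC")
})

test_that("fit-AUC-Ra pipeline recovers known truth on a small cohort", {
  cfg <- sim_config(group_sizes = c("LBW-Gln" = 12L, "NBW-Gln" = 12L,
                                    "LBW-W" = 11L, "NBW-W" = 11L),
                    analytes = c("Gln-m5", "Glc-m6"))
  co <- simulate_cohort(cfg, seed = 2027)
  res <- analyze_cohort(co$curves)
  m <- merge(res$kinetics, co$truth, by = "animal_id", suffixes = c("_est", "_true"))
  expect_equal(nrow(m), 46L)
  expect_lt(median(abs(m$ra_gln_est / m$ra_gln_true - 1)), 0.05)
  expect_lt(median(abs(m$ra_glc_est / m$ra_glc_true - 1)), 0.05)
  expect_true(all(m$ra_gln_est > 0 & m$ra_glc_est > 0))
})
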