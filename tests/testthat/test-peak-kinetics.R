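test_that("noiseless Bateman data are recovered to high accuracy", {
  # plasma glutamine-tracer peak used as simulation truth
  p <- bateman_from_peak(emax = 1.18, tmax = 31.3, rho = 10)
  cu <- simulate_enrichment_curve(p, study_schedule, noise_cv = 0, basal_sd = 0,
                                  unit = "MPE")
  fit <- fit_peak_model(cu)
  expect_true(fit$converged)
  expect_equal(fit$emax, 1.18, tolerance = 1e-3)       # within 0.1%
  expect_equal(fit$tmax, 31.3, tolerance = 0.5 / 31.3) # within 0.5 min
  expect_equal(fit$auc, bateman_auc(p$A, p$ka, p$ke), tolerance = 1e-6)
})

test_that("a lagged curve with a sampled rise recovers its lag", {
  p <- bateman_from_auc(15.4, 75, rho = 10, t0 = 15)
  cu <- simulate_enrichment_curve(p, study_schedule, unit = "APE")
  fit <- fit_peak_model(cu, families = "bateman")
  expect_true(fit$converged)
  expect_equal(fit$tmax, 75, tolerance = 1e-3)
  expect_equal(unname(fit$params["t0"]), 15, tolerance = 0.05)
})

test_that("short or flat series fall back to the empirical summary", {
  # symmetric triangle peaking at t = 100, too short to fit
  tri <- data.frame(time_min = c(50, 100, 150, 200),
                    value = c(0.5, 1.0, 0.5, 0.0))
  fit <- fit_peak_model(tri)
  expect_false(fit$converged)
  expect_identical(fit$family, "empirical")
  expect_equal(fit$tmax, 100)
  expect_equal(fit$emax, 1.0)

  # flat series: earliest time of the maximum
  flat <- data.frame(time_min = post_schedule, value = rep(2, 9))
  ffit <- fit_peak_model(flat)
  expect_false(ffit$converged)
  expect_equal(ffit$tmax, 30)
  expect_equal(ffit$emax, 2)
})

test_that("analytic Bateman AUC matches adaptive quadrature to 1e-8 relative", {
  for (p in random_bateman_params(20)) {
    analytic <- bateman_auc(p$A, p$ka, p$ke, p$t0)
    numeric <- quadrature_auc(function(t) bateman_value(t, p$A, p$ka, p$ke, p$t0),
                              kink = p$t0)
    expect_equal(analytic, numeric, tolerance = 1e-8)
  }
})

test_that("log-normal and gamma-variate closed-form AUCs match quadrature", {
  expect_equal(lognormal_peak_auc(1.2, 40, 0.7),
               quadrature_auc(function(t) lognormal_peak_value(t, 1.2, 40, 0.7)),
               tolerance = 1e-8)
  expect_equal(gamma_variate_auc(0.003, 2.5, 30, 10),
               quadrature_auc(function(t) gamma_variate_value(t, 0.003, 2.5, 30, 10),
                              kink = 10),
               tolerance = 1e-8)
})

test_that("closed-form Bateman Tmax agrees with a fine grid argmax", {
  grid <- seq(0, 300, by = 0.01)
  for (p in random_bateman_params(100, seed = 505)) {
    tm <- bateman_tmax(p$ka, p$ke, p$t0)
    if (tm >= 300) next
    y <- bateman_value(grid, p$A, p$ka, p$ke, p$t0)
    expect_lt(abs(tm - grid[which.max(y)]), 0.02)
  }
})

test_that("the degenerate ka = ke limit form is continuous", {
  t <- c(10, 50, 150)
  near <- bateman_value(t, A = 1e6, ka = 0.02 + 1e-12, ke = 0.02)
  lim <- bateman_limit_value(t, A = 1e6 * 1e-12, k = 0.02)
  # tolerance limited by cancellation in ka - ke at the degeneracy
  expect_equal(near, lim, tolerance = 1e-4)
})

test_that("trapezoid AUC handles the implied zero at bolus time", {
  # constant 1.0 observed from 30 min: 285 = 300 minus the 0-30 triangle
  expect_equal(auc_trapezoid(post_schedule, rep(1, 9)), 285)
  expect_equal(auc_trapezoid(post_schedule, rep(0, 9)), 0)
  expect_error(auc_trapezoid(c(30, 20, 60), c(1, 2, 3)), "increasing")

  # dense grid approaches the analytic value
  p <- bateman_from_peak(1.0, 45, rho = 8)
  tt <- seq(1, 300, by = 1)
  expect_equal(auc_trapezoid(tt, bateman_value(tt, p$A, p$ka, p$ke)),
               bateman_auc(p$A, p$ka, p$ke), tolerance = 5e-4)
})

test_that("Emax and AUC are homogeneous in curve scale; Tmax is invariant", {
  p <- bateman_from_peak(0.9, 50, rho = 10)
  set.seed(31)
  y <- bateman_value(post_schedule, p$A, p$ka, p$ke) * exp(stats::rnorm(9, 0, 0.03))
  f1 <- fit_peak_model(data.frame(time_min = post_schedule, value = y))
  f2 <- fit_peak_model(data.frame(time_min = post_schedule, value = 2 * y))
  expect_equal(f2$emax, 2 * f1$emax, tolerance = 1e-6)
  expect_equal(f2$auc, 2 * f1$auc, tolerance = 1e-6)
  expect_equal(f2$tmax, f1$tmax, tolerance = 1e-6)
  expect_equal(auc_trapezoid(post_schedule, 2 * y),
               2 * auc_trapezoid(post_schedule, y))
})

test_that("model and trapezoid AUC agree within 10% at study noise levels", {
  set.seed(77)
  p <- bateman_from_auc(150, 40, rho = 10)
  y0 <- bateman_value(post_schedule, p$A, p$ka, p$ke)
  # at the study's 5% CV every replicate agrees within 10%
  s5 <- sqrt(log(1 + 0.05^2))
  for (i in 1:20) {
    y <- y0 * exp(stats::rnorm(9, 0, s5) - s5^2 / 2)
    fit <- fit_peak_model(data.frame(time_min = post_schedule, value = y))
    expect_lt(abs(fit$auc / fit$auc_trap - 1), 0.10)
  }
  # at 10% CV the typical disagreement still stays within 10%
  s10 <- sqrt(log(1 + 0.10^2))
  d <- vapply(1:20, function(i) {
    y <- y0 * exp(stats::rnorm(9, 0, s10) - s10^2 / 2)
    fit <- fit_peak_model(data.frame(time_min = post_schedule, value = y))
    abs(fit$auc / fit$auc_trap - 1)
  }, numeric(1))
  expect_lt(median(d), 0.10)
})

test_that("summarize_fit converts AUC between min and h scales", {
  p <- bateman_from_auc(164, 31.3, rho = 10)
  cu <- simulate_enrichment_curve(p, study_schedule, unit = "MPE",
                                  animal_id = "P001", analyte = "Gln-m5")
  row <- summarize_fit(fit_peak_model(cu))
  expect_equal(row$AUC_unit_min, 164, tolerance = 1e-4)
  expect_equal(row$AUC_unit_h, 164 / 60, tolerance = 1e-4)
  expect_equal(row$AUC_unit_h, 2.733, tolerance = 1e-3)
  expect_identical(row$animal_id, "P001")
})
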