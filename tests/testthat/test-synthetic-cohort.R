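test_that("noiseless simulation equals the deterministic Bateman evaluation", {
  p <- bateman_from_peak(1.18, 31.3, rho = 10)
  cu <- simulate_enrichment_curve(p, study_schedule, noise_cv = 0, basal_sd = 0)
  expect_equal(cu$value[1], 0)   # basal
  expect_equal(cu$value[-1],
               bateman_value(post_schedule, p$A, p$ka, p$ke, p$t0))
  # the generated curve peaks near (30, ~1.18) on the study schedule
  imax <- which.max(cu$value)
  expect_equal(cu$time_min[imax], 30)
  expect_equal(cu$value[imax], 1.18, tolerance = 0.015)
})

test_that("measurement noise is mean-preserving", {
  p <- bateman_from_peak(1.0, 45, rho = 10)
  e60 <- bateman_value(60, p$A, p$ka, p$ke)
  set.seed(606)
  draws <- vapply(seq_len(10000), function(i) {
    cu <- simulate_enrichment_curve(p, c(-15, 60), noise_cv = 0.10)
    cu$value[cu$time_min == 60]
  }, numeric(1))
  expect_equal(mean(draws), e60, tolerance = 0.01)
})

test_that("the default cohort reproduces the study layout", {
  co <- simulate_cohort(sim_config(), seed = 42)
  expect_equal(nrow(co$animals), 46L)
  expect_equal(as.integer(table(co$animals$group)[c("LBW-Gln", "NBW-Gln", "LBW-W", "NBW-W")]),
               c(12L, 12L, 11L, 11L))
  expect_lte(length(unique(co$animals$litter_id)), 18L)
  # birthweight class windows
  lbw <- co$animals$birthweight_kg[co$animals$biw_class == "LBW"]
  nbw <- co$animals$birthweight_kg[co$animals$biw_class == "NBW"]
  expect_true(all(lbw >= 0.8 & lbw <= 1.2))
  expect_true(all(nbw >= 1.4 & nbw <= 1.8))
  # every animal has a curve for each administered analyte (total joins)
  combos <- unique(co$curves[, c("animal_id", "analyte")])
  expect_equal(nrow(combos), 46L * 8L)
  expect_setequal(unique(combos$analyte), co$config$analytes)
  # truth aligns one-to-one with animals
  expect_setequal(co$truth$animal_id, co$animals$animal_id)
  expect_true(all(co$truth$ra_gln > 0))
  expect_true(all(co$truth$rec_gln > 0))
})

test_that("identical seeds give identical tables; different seeds differ", {
  cfg <- sim_config(group_sizes = c("LBW-Gln" = 3L, "NBW-Gln" = 3L,
                                    "LBW-W" = 3L, "NBW-W" = 3L),
                    analytes = c("Gln-m5", "xylose"))
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(a$curves, b$curves)
  expect_identical(a$truth, b$truth)
  expect_identical(a$animals, b$animals)
  c2 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$curves, c2$curves))
})

test_that("simulated lactulose stays below its LOQ as in the study", {
  co <- simulate_cohort(sim_config(analytes = "lactulose"), seed = 3)
  cfg <- sugar_test_config("lactulose")
  post <- co$curves[co$curves$time_min > 0, ]
  for (id in unique(post$animal_id)) {
    sub <- post[post$animal_id == id, ]
    cs <- censor_loq(sub$time_min, sub$value, cfg)
    expect_true(attr(cs, "all_below_loq"))
  }
})

test_that("truth-table group means track the configured cell means", {
  # many litters so the litter-level sampling error of the mean averages out
  cfg <- sim_config(group_sizes = c("LBW-Gln" = 400L, "NBW-Gln" = 400L,
                                    "LBW-W" = 400L, "NBW-W" = 400L),
                    n_litters = 400L, analytes = character(0))
  co <- simulate_cohort(cfg, seed = 17)
  gm <- default_group_means()
  for (g in gm$group) {
    i <- co$truth$group == g
    expect_equal(mean(co$truth$ra_gln[i]), gm$ra_gln[gm$group == g],
                 tolerance = 0.05)
    expect_equal(mean(co$truth$ra_glc[i]), gm$ra_glc[gm$group == g],
                 tolerance = 0.05)
  }
  # recovery scorer identity: a noiseless cohort is recovered (near) exactly
  cfg0 <- sim_config(group_sizes = c("LBW-Gln" = 2L, "NBW-Gln" = 2L,
                                     "LBW-W" = 2L, "NBW-W" = 2L),
                     noise_cv = 0, basal_noise_sd = 0,
                     analytes = c("Gln-m5", "Glc-m6"))
  co0 <- simulate_cohort(cfg0, seed = 5)
  res0 <- analyze_cohort(co0$curves)
  m0 <- merge(res0$kinetics, co0$truth, by = "animal_id", suffixes = c("_est", "_true"))
  expect_equal(median(abs(m0$ra_gln_est / m0$ra_gln_true - 1)), 0, tolerance = 1e-5)
})
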