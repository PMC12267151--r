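#' Default per-cell kinetic ground truth for the simulated cohort
#'
#' Group-mean kinetic parameters for the four cells of the 2x2 factorial
#' (birthweight class LBW/NBW x supplementation Gln/W). Tracer targets —
#' rate of appearance, peak times, gluconeogenic conversion, CO2 enrichment
#' AUCs, xylose peak — are the study's printed group means; the mannitol and
#' lactulose targets are plausible values chosen so that mannitol is well
#' quantifiable while lactulose stays below its 0.03 mmol/L LOQ, mirroring
#' the observed all-censored lactulose outcome. Bodyweight columns give the
#' birthweight-class means and per-group average daily gains.
#'
#' @return data frame, one row per cell (`LBW-Gln`, `NBW-Gln`, `LBW-W`,
#'   `NBW-W`).
#' @export
default_group_means <- function() {
  data.frame(
    group = c("LBW-Gln", "NBW-Gln", "LBW-W", "NBW-W"),
    biw_class = c("LBW", "NBW", "LBW", "NBW"),
    supplementation = c("Gln", "Gln", "W", "W"),
    ra_gln = c(2.68, 3.11, 3.07, 2.62),        # mmol/(kg h)
    tmax_gln = c(31.3, 37.8, 36.6, 29.1),      # min
    ra_glc = c(5.63, 5.48, 5.07, 6.61),
    tmax_glc = c(49.6, 58.2, 50.3, 50.2),
    conv_pct = c(8.24, 9.78, 10.4, 7.37),      # Gln -> Glc conversion %
    tmax_m3 = c(56.8, 75.1, 61.6, 56.5),
    auc_co2_gln = c(15.4, 14.2, 16.1, 14.5),   # APE x min
    tmax_co2_gln = c(59.1, 80.0, 74.9, 61.1),
    auc_co2_glc = c(13.7, 13.8, 12.7, 10.1),
    tmax_co2_glc = c(116, 144, 125, 120),
    emax_xyl = c(1.35, 1.27, 1.21, 0.92),      # mmol/L
    tmax_xyl = c(60.6, 101, 60.3, 72.8),
    emax_man = c(0.30, 0.25, 0.28, 0.26),
    tmax_man = c(90, 110, 95, 100),
    emax_lac = c(0.012, 0.012, 0.012, 0.012),  # below the 0.03 LOQ
    tmax_lac = c(120, 120, 120, 120),
    biw_kg = c(1.04, 1.55, 1.04, 1.55),
    adg_kg_d = c(0.17, 0.24, 0.19, 0.24),
    crl_m = c(0.26, 0.30, 0.26, 0.30),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Study conditions for the synthetic cohort: the 2x2 factorial with cell
#' sizes 12/12/11/11 drawn from 18 litters as LBW/NBW littermate pairs, the
#' ten-point sampling schedule (-15 min basal; 30-300 min post bolus),
#' multiplicative log-normal measurement noise (CV 5%), log-scale litter and
#' animal random effects, Bateman curve shapes with a fixed
#' absorption/elimination rate ratio, and the default tracer doses.
#'
#' @param group_sizes named integer vector of cell sizes.
#' @param n_litters number of litters supplying littermate pairs.
#' @param schedule_min sampling times (min); must include `basal_time`.
#' @param noise_cv multiplicative measurement noise CV (log-normal,
#'   mean-preserving).
#' @param litter_sd,animal_sd log-scale SDs of the litter random intercept
#'   and the per-animal deviation applied to kinetic parameters.
#' @param shape_ratio Bateman ka/ke ratio used for all generated curves.
#' @param t0_co2 lag (min) of the delayed CO2-enrichment response.
#' @param basal_noise_sd absolute SD of the basal-sample noise floor (curve
#'   units).
#' @param group_means per-cell truth table, see [default_group_means()].
#' @param doses list with `gln` and `glc` [tracer_dose()] objects.
#' @param r_co2 CO2 production rate, mmol/(kg x h).
#' @param normalization named RBC-to-breath factors (`gln`, `glc`).
#' @param analytes which analytes to simulate (default all eight).
#' @param basal_time time of the basal sample (min).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(group_sizes = c("LBW-Gln" = 12L, "NBW-Gln" = 12L,
                                       "LBW-W" = 11L, "NBW-W" = 11L),
                       n_litters = 18L,
                       schedule_min = c(-15, 30, 60, 90, 120, 150, 180, 210, 240, 300),
                       noise_cv = 0.05, litter_sd = 0.15, animal_sd = 0.25,
                       shape_ratio = 10, t0_co2 = 15, basal_noise_sd = 0.005,
                       group_means = default_group_means(),
                       doses = list(gln = gln_tracer_dose(), glc = glc_tracer_dose()),
                       r_co2 = 48,
                       normalization = c(gln = 0.90, glc = 0.98),
                       analytes = c("Gln-m5", "Glc-m3", "CO2-Gln", "Glc-m6",
                                    "CO2-Glc", "xylose", "mannitol", "lactulose"),
                       basal_time = -15) {
  stopifnot(all(group_sizes >= 1L), n_litters >= 1L, noise_cv >= 0,
            litter_sd >= 0, animal_sd >= 0, shape_ratio > 1,
            basal_time %in% schedule_min,
            !is.null(names(group_sizes)),
            all(names(group_sizes) %in% group_means$group))
  structure(list(group_sizes = group_sizes, n_litters = as.integer(n_litters),
                 schedule_min = schedule_min, noise_cv = noise_cv,
                 litter_sd = litter_sd, animal_sd = animal_sd,
                 shape_ratio = shape_ratio, t0_co2 = t0_co2,
                 basal_noise_sd = basal_noise_sd, group_means = group_means,
                 doses = doses, r_co2 = r_co2, normalization = normalization,
                 analytes = analytes, basal_time = basal_time),
            class = "sim_config")
}

#' Simulate one enrichment (or concentration) curve
#'
#' Evaluates a Bateman curve on the sampling schedule and applies
#' mean-preserving multiplicative log-normal noise (`x exp(z - s^2/2)`,
#' `z ~ N(0, s^2)`, `s^2 = log(1 + cv^2)`) to the post-bolus points; the
#' basal point is drawn as zero plus an absolute noise floor. With
#' `noise_cv = 0` and `basal_sd = 0` the curve is the deterministic Bateman
#' evaluation.
#'
#' @param params named list/vector with `A`, `ka`, `ke`, `t0` (see
#'   [bateman_value()]).
#' @param schedule sampling times (min) including the basal time.
#' @param noise_cv multiplicative noise CV.
#' @param basal_sd absolute SD of the basal noise floor.
#' @param basal_time basal sample time (min).
#' @param nonnegative clamp sampled values at 0 (used for concentrations).
#' @inheritParams enrichment_curve
#' @return an [enrichment_curve()].
#' @export
simulate_enrichment_curve <- function(params, schedule, noise_cv = 0,
                                      basal_sd = 0, basal_time = -15,
                                      nonnegative = FALSE,
                                      animal_id = NA_character_,
                                      analyte = NA_character_, unit = "MPE") {
  p <- as.list(params)
  stopifnot(p$A > 0, p$ka > 0, p$ke > 0)
  post <- schedule[schedule != basal_time]
  y <- bateman_value(post, p$A, p$ka, p$ke, p$t0)
  if (noise_cv > 0) {
    slog <- sqrt(log(1 + noise_cv^2))
    y <- y * exp(stats::rnorm(length(y), 0, slog) - slog^2 / 2)
  }
  basal <- if (basal_sd > 0) stats::rnorm(1, 0, basal_sd) else 0
  tt <- c(basal_time, post)
  vv <- c(basal, y)
  if (nonnegative) vv <- pmax(vv, 0)
  o <- order(tt)
  enrichment_curve(tt[o], vv[o], animal_id = animal_id, analyte = analyte,
                   unit = unit, basal_time = basal_time)
}

# mean-preserving log-normal draw around per-animal cell means with a shared
# litter intercept
.draw_param <- function(mean_i, litter_eff_i, animal_sd, litter_sd) {
  n <- length(mean_i)
  tot_var <- animal_sd^2 + litter_sd^2
  mean_i * exp(litter_eff_i + stats::rnorm(n, 0, animal_sd) - tot_var / 2)
}

#' Simulate a complete factorial tracer-study cohort
#'
#' Builds the full synthetic dataset with known ground truth:
#' \enumerate{
#'   \item Animals are created as LBW/NBW littermate pairs within each
#'     supplementation arm, pairs assigned to litters cyclically.
#'   \item One litter random intercept per litter (log scale) plus
#'     independent per-animal deviations scale every kinetic parameter;
#'     draws are mean-centred so configured cell means are the expected
#'     truth means.
#'   \item Plasma tracer curves are Bateman-shaped, parameterized by the
#'     drawn (Ra, Tmax): the enrichment AUC follows from the dose relation
#'     `AUC = D/Ra x 100` (MPE x h) and the amplitude is solved so the
#'     windowed AUC matches. The 13C3-glucose curve is scaled by the drawn
#'     conversion; CO2 curves are delayed Batemans matched to the drawn
#'     CO2 AUC and Tmax; sugar-probe curves are matched to (Emax, Tmax),
#'     with lactulose below its LOQ by default.
#'   \item Bodyweight trajectories are linear in age with per-group ADG.
#' }
#' Identical `seed` and config give byte-identical tables.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return object of class `cohort_tables`: list with `animals`, `weights`
#'   (long bodyweight-by-day), `curves` (long), `truth` (per-animal ground
#'   truth), `config`, `seed`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  gm <- cfg$group_means
  rownames(gm) <- gm$group

  ## -- animals and litters ------------------------------------------------
  groups <- names(cfg$group_sizes)
  cells <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g,
               biw_class = gm[g, "biw_class"],
               supplementation = gm[g, "supplementation"],
               idx = seq_len(cfg$group_sizes[[g]]),
               stringsAsFactors = FALSE)
  }))
  # littermate pairing: pair j of each supplementation arm holds the j-th
  # LBW and j-th NBW animal; pairs map to litters cyclically, W pairs offset
  # past the Gln pairs
  supp_levels <- unique(cells$supplementation)
  offset <- 0L
  cells$litter_id <- NA_integer_
  for (s in supp_levels) {
    i <- cells$supplementation == s
    cells$litter_id[i] <- ((offset + cells$idx[i] - 1L) %% cfg$n_litters) + 1L
    offset <- offset + max(cells$idx[i])
  }
  n <- nrow(cells)
  animals <- data.frame(
    animal_id = sprintf("P%03d", seq_len(n)),
    litter_id = sprintf("L%02d", cells$litter_id),
    biw_class = cells$biw_class,
    supplementation = cells$supplementation,
    group = cells$group,
    stringsAsFactors = FALSE
  )
  lo <- ifelse(animals$biw_class == "LBW", 0.8, 1.4)
  hi <- ifelse(animals$biw_class == "LBW", 1.2, 1.8)
  animals$birthweight_kg <- pmin(pmax(
    stats::rnorm(n, gm[animals$group, "biw_kg"], 0.08), lo), hi)
  animals$crl_m <- abs(stats::rnorm(n, gm[animals$group, "crl_m"], 0.01))
  animals$abc_m <- abs(stats::rnorm(n, ifelse(animals$biw_class == "LBW", 0.22, 0.26), 0.01))
  bi <- body_indices(animals$birthweight_kg, animals$crl_m)
  animals$bmi_kg_m2 <- bi$bmi_kg_m2
  animals$pi_kg_m3 <- bi$pi_kg_m3

  days <- 1:16
  adg <- gm[animals$group, "adg_kg_d"]
  weights <- data.frame(
    animal_id = rep(animals$animal_id, each = length(days)),
    day = rep(days, times = n),
    bw_kg = rep(animals$birthweight_kg, each = length(days)) +
      rep(adg, each = length(days)) * (rep(days, times = n) - 1) +
      stats::rnorm(n * length(days), 0, 0.02)
  )

  ## -- per-animal kinetic parameter draws ---------------------------------
  litters <- sort(unique(animals$litter_id))
  litter_int <- stats::setNames(stats::rnorm(length(litters), 0, cfg$litter_sd), litters)
  L <- litter_int[animals$litter_id]
  mu <- function(col) gm[animals$group, col]
  dp <- function(col) .draw_param(mu(col), L, cfg$animal_sd, cfg$litter_sd)
  # fixed draw order (reproducibility contract)
  truth <- data.frame(animal_id = animals$animal_id, group = animals$group,
                      stringsAsFactors = FALSE)
  truth$ra_gln <- dp("ra_gln")
  truth$tmax_gln <- pmin(pmax(dp("tmax_gln"), 16), 250)
  truth$conv_pct <- dp("conv_pct")
  truth$tmax_m3 <- pmin(pmax(dp("tmax_m3"), 16), 250)
  truth$auc_co2_gln <- dp("auc_co2_gln")
  truth$tmax_co2_gln <- pmin(pmax(dp("tmax_co2_gln"), cfg$t0_co2 + 10), 280)
  truth$ra_glc <- dp("ra_glc")
  truth$tmax_glc <- pmin(pmax(dp("tmax_glc"), 16), 250)
  truth$auc_co2_glc <- dp("auc_co2_glc")
  truth$tmax_co2_glc <- pmin(pmax(dp("tmax_co2_glc"), cfg$t0_co2 + 10), 280)
  truth$emax_xyl <- dp("emax_xyl")
  truth$tmax_xyl <- pmin(pmax(dp("tmax_xyl"), 16), 250)
  truth$emax_man <- dp("emax_man")
  truth$tmax_man <- pmin(pmax(dp("tmax_man"), 16), 250)
  truth$emax_lac <- dp("emax_lac")
  truth$tmax_lac <- pmin(pmax(dp("tmax_lac"), 16), 250)

  window <- c(0, max(cfg$schedule_min))
  D_gln <- dose_to_mmol(cfg$doses$gln)
  D_glc <- dose_to_mmol(cfg$doses$glc)
  # enrichment AUCs implied by the drawn Ra (MPE x min over the window)
  truth$auc_gln <- D_gln / truth$ra_gln * 100 * 60
  truth$auc_glc <- D_glc / truth$ra_glc * 100 * 60
  truth$auc_m3 <- truth$conv_pct / 100 * truth$auc_gln
  truth$rec_gln <- c13_recovery(truth$auc_co2_gln, tracer_excess_13c(cfg$doses$gln),
                                r_co2 = cfg$r_co2,
                                normalization = cfg$normalization[["gln"]])
  truth$rec_glc <- c13_recovery(truth$auc_co2_glc, tracer_excess_13c(cfg$doses$glc),
                                r_co2 = cfg$r_co2,
                                normalization = cfg$normalization[["glc"]])
  attributes(truth$rec_gln) <- NULL
  attributes(truth$rec_glc) <- NULL

  curve_specs <- list(
    "Gln-m5"  = list(unit = "MPE", type = "enrichment",
                     par = function(i) bateman_from_auc(truth$auc_gln[i], truth$tmax_gln[i],
                                                        cfg$shape_ratio, 0, window)),
    "Glc-m3"  = list(unit = "MPE", type = "enrichment",
                     par = function(i) bateman_from_auc(truth$auc_m3[i], truth$tmax_m3[i],
                                                        cfg$shape_ratio, 0, window)),
    "CO2-Gln" = list(unit = "APE", type = "enrichment",
                     par = function(i) bateman_from_auc(truth$auc_co2_gln[i], truth$tmax_co2_gln[i],
                                                        cfg$shape_ratio, cfg$t0_co2, window)),
    "Glc-m6"  = list(unit = "MPE", type = "enrichment",
                     par = function(i) bateman_from_auc(truth$auc_glc[i], truth$tmax_glc[i],
                                                        cfg$shape_ratio, 0, window)),
    "CO2-Glc" = list(unit = "APE", type = "enrichment",
                     par = function(i) bateman_from_auc(truth$auc_co2_glc[i], truth$tmax_co2_glc[i],
                                                        cfg$shape_ratio, cfg$t0_co2, window)),
    "xylose"   = list(unit = "mmol/L", type = "concentration",
                      par = function(i) bateman_from_peak(truth$emax_xyl[i], truth$tmax_xyl[i],
                                                          cfg$shape_ratio, 0)),
    "mannitol" = list(unit = "mmol/L", type = "concentration",
                      par = function(i) bateman_from_peak(truth$emax_man[i], truth$tmax_man[i],
                                                          cfg$shape_ratio, 0)),
    "lactulose" = list(unit = "mmol/L", type = "concentration",
                       par = function(i) bateman_from_peak(truth$emax_lac[i], truth$tmax_lac[i],
                                                           cfg$shape_ratio, 0))
  )

  ## -- curves --------------------------------------------------------------
  curve_list <- list()
  for (an in cfg$analytes) {
    spec <- curve_specs[[an]]
    if (is.null(spec)) stop("unknown analyte in config: ", an)
    conc <- spec$type == "concentration"
    for (i in seq_len(n)) {
      p <- spec$par(i)
      cu <- simulate_enrichment_curve(
        p, cfg$schedule_min, noise_cv = cfg$noise_cv,
        basal_sd = cfg$basal_noise_sd, basal_time = cfg$basal_time,
        nonnegative = conc, animal_id = animals$animal_id[i], analyte = an,
        unit = spec$unit)
      curve_list[[length(curve_list) + 1L]] <- data.frame(
        animal_id = animals$animal_id[i], analyte = an, unit = spec$unit,
        measurement_type = spec$type,
        time_min = cu$time_min, value = cu$value,
        stringsAsFactors = FALSE)
    }
  }
  curves <- if (length(curve_list)) do.call(rbind, curve_list) else
    data.frame(animal_id = character(0), analyte = character(0),
               unit = character(0), measurement_type = character(0),
               time_min = numeric(0), value = numeric(0))
  rownames(curves) <- NULL

  structure(list(animals = animals, weights = weights, curves = curves,
                 truth = truth, config = cfg, seed = seed),
            class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat(sprintf("<cohort_tables> %d animals (%s), %d curve rows, %d analytes, seed %d\n",
              nrow(x$animals),
              paste(sprintf("%s=%d", names(x$config$group_sizes), x$config$group_sizes),
                    collapse = ", "),
              nrow(x$curves), length(unique(x$curves$analyte)), x$seed))
  invisible(x)
}

#' Extract the ground-truth table of a simulated cohort
#'
#' Per-animal true kinetic parameters (Ra, conversion %, recovery %, AUCs,
#' peak targets), joinable on `animal_id` for recovery scoring against
#' pipeline estimates.
#' @param tables a `cohort_tables` object from [simulate_cohort()].
#' @return data frame.
#' @export
ground_truth_table <- function(tables) {
  stopifnot(inherits(tables, "cohort_tables"))
  tables$truth
}
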