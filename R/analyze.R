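#' Curve table to enrichment_curve objects
#'
#' Splits a long curve table (columns `animal_id`, `analyte`, `unit`,
#' `time_min`, `value`) into [enrichment_curve()] objects.
#' @param curves long-format data frame.
#' @param basal_time basal sample time (min).
#' @return named list of `enrichment_curve` keyed `animal_id.analyte`.
#' @keywords internal
split_curves <- function(curves, basal_time = -15) {
  need <- c("animal_id", "analyte", "time_min", "value")
  miss <- setdiff(need, names(curves))
  if (length(miss)) stop("curve table is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (key in unique(paste(curves$animal_id, curves$analyte, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- curves[curves$animal_id == parts[1] & curves$analyte == parts[2], ]
    sub <- sub[order(sub$time_min), ]
    unit <- if ("unit" %in% names(sub)) sub$unit[1] else "MPE"
    out[[paste(parts, collapse = ".")]] <- enrichment_curve(
      sub$time_min, sub$value, animal_id = parts[1], analyte = parts[2],
      unit = unit, basal_time = basal_time)
  }
  out
}

#' Run the kinetic estimation pipeline on a cohort's curves
#'
#' The fit-AUC-endpoint stage: every tracer enrichment curve is
#' baseline-corrected and fitted with [fit_peak_model()]; per-animal
#' endpoints are then assembled — rate of appearance for the glutamine and
#' glucose tracers, 13C recovery from the CO2 curves, and gluconeogenic
#' conversion from the 13C3-glucose / 13C5-glutamine AUC quotient. Sugar
#' probes are LOQ-censored and summarized through the same peak machinery.
#'
#' @param curves long curve table (e.g. `cohort$curves` from
#'   [simulate_cohort()], or read from CSV).
#' @param doses list with `gln` and `glc` [tracer_dose()] objects.
#' @param rec_mode recovery mode, `"dimensional"` or `"literal"`.
#' @param auc_method `"model"` (closed form from the winning fit, default)
#'   or `"trapezoid"`.
#' @param families peak families passed to [fit_peak_model()].
#' @param window AUC window (min).
#' @param r_co2,t_hours,normalization recovery settings, see
#'   [c13_recovery()].
#' @param basal_time basal sample time (min).
#' @return list with `fits` (per animal x analyte fit summaries),
#'   `kinetics` (per-animal Ra / recovery / conversion), `sugars`
#'   (absorption-test summaries), and `settings`.
#' @export
analyze_cohort <- function(curves,
                           doses = list(gln = gln_tracer_dose(), glc = glc_tracer_dose()),
                           rec_mode = c("dimensional", "literal"),
                           auc_method = c("model", "trapezoid"),
                           families = c("bateman", "lognormal_peak", "gamma_variate"),
                           window = c(0, 300), r_co2 = 48, t_hours = 5,
                           normalization = c(gln = 0.90, glc = 0.98),
                           basal_time = -15) {
  rec_mode <- match.arg(rec_mode)
  auc_method <- match.arg(auc_method)
  tracer_analytes <- c("Gln-m5", "Glc-m3", "CO2-Gln", "Glc-m6", "CO2-Glc")
  sugar_analytes <- c("xylose", "mannitol", "lactulose")

  present <- unique(curves$analyte)
  clist <- split_curves(curves[curves$analyte %in% tracer_analytes, , drop = FALSE],
                        basal_time)
  fits <- list(); aucs <- list()
  for (key in names(clist)) {
    fit <- fit_peak_model(clist[[key]], families = families, window = window)
    fits[[key]] <- summarize_fit(fit)
    aucs[[key]] <- if (auc_method == "model" && fit$converged) fit$auc else fit$auc_trap
  }
  fits <- if (length(fits)) do.call(rbind, c(fits, make.row.names = FALSE)) else NULL

  get_auc <- function(id, analyte) {
    v <- aucs[[paste(id, analyte, sep = ".")]]
    if (is.null(v)) NA_real_ else v
  }
  ids <- unique(curves$animal_id)
  kin <- data.frame(animal_id = ids, stringsAsFactors = FALSE)
  kin$auc_gln <- vapply(ids, get_auc, 0, analyte = "Gln-m5")
  kin$auc_glc <- vapply(ids, get_auc, 0, analyte = "Glc-m6")
  kin$auc_m3 <- vapply(ids, get_auc, 0, analyte = "Glc-m3")
  kin$auc_co2_gln <- vapply(ids, get_auc, 0, analyte = "CO2-Gln")
  kin$auc_co2_glc <- vapply(ids, get_auc, 0, analyte = "CO2-Glc")
  D_gln <- dose_to_mmol(doses$gln); D_glc <- dose_to_mmol(doses$glc)
  safe <- function(f, ...) tryCatch(f(...), error = function(e) NA_real_)
  kin$ra_gln <- vapply(kin$auc_gln, function(a)
    safe(rate_of_appearance, D_gln, a, auc_unit = "MPE_min"), 0)
  kin$ra_glc <- vapply(kin$auc_glc, function(a)
    safe(rate_of_appearance, D_glc, a, auc_unit = "MPE_min"), 0)
  kin$conv_pct <- ifelse(is.na(kin$auc_m3) | is.na(kin$auc_gln) | kin$auc_gln <= 0,
                         NA_real_, 100 * kin$auc_m3 / kin$auc_gln)
  ex_gln <- tracer_excess_13c(doses$gln); ex_glc <- tracer_excess_13c(doses$glc)
  kin$rec_gln <- vapply(kin$auc_co2_gln, function(a)
    if (is.na(a)) NA_real_ else as.numeric(
      c13_recovery(a, ex_gln, r_co2 = r_co2, t_hours = t_hours,
                   normalization = normalization[["gln"]], mode = rec_mode)), 0)
  kin$rec_glc <- vapply(kin$auc_co2_glc, function(a)
    if (is.na(a)) NA_real_ else as.numeric(
      c13_recovery(a, ex_glc, r_co2 = r_co2, t_hours = t_hours,
                   normalization = normalization[["glc"]], mode = rec_mode)), 0)
  kin$rec_mode <- rec_mode
  # drop all-NA endpoint rows for animals that only have sugar curves
  has_tracer <- rowSums(!is.na(kin[, c("auc_gln", "auc_glc", "auc_m3",
                                       "auc_co2_gln", "auc_co2_glc")])) > 0
  kin <- kin[has_tracer, , drop = FALSE]
  rownames(kin) <- NULL

  sugars <- NULL
  sug_present <- intersect(sugar_analytes, present)
  if (length(sug_present)) {
    rows <- list()
    for (an in sug_present) {
      cfg <- sugar_test_config(an)
      sub_all <- curves[curves$analyte == an, , drop = FALSE]
      for (id in unique(sub_all$animal_id)) {
        sub <- sub_all[sub_all$animal_id == id, ]
        sub <- sub[order(sub$time_min), ]
        cs <- censor_loq(sub$time_min, sub$value, cfg)
        sm <- absorption_summary(cs, families = families, window = window)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, analyte = an,
          quantifiable = sm$quantifiable,
          Emax = if (sm$quantifiable) sm$Emax else NA_real_,
          Tmax_min = if (sm$quantifiable) sm$Tmax_min else NA_real_,
          AUC_mmol_L_min = if (sm$quantifiable) sm$AUC_mmol_L_min else NA_real_,
          n_censored = sm$n_censored,
          stringsAsFactors = FALSE)
      }
    }
    sugars <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  list(fits = fits, kinetics = kin, sugars = sugars,
       settings = list(rec_mode = rec_mode, auc_method = auc_method,
                       families = families, window = window, r_co2 = r_co2,
                       t_hours = t_hours, normalization = normalization))
}

#' Group-level summary of per-animal kinetic results
#'
#' Cell means and SEMs of the kinetic endpoints by factorial group.
#' @param kinetics per-animal table from [analyze_cohort()].
#' @param animals animal metadata with `animal_id` and `group`.
#' @return data frame, one row per group x endpoint, with `mean`, `sem`,
#'   `n`.
#' @export
group_summary <- function(kinetics, animals) {
  m <- merge(kinetics, animals[, c("animal_id", "group")], by = "animal_id")
  vars <- intersect(c("ra_gln", "ra_glc", "conv_pct", "rec_gln", "rec_glc",
                      "auc_gln", "auc_glc", "auc_m3", "auc_co2_gln", "auc_co2_glc"),
                    names(m))
  rows <- list()
  for (g in sort(unique(m$group))) {
    for (v in vars) {
      x <- m[m$group == g, v]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, mean = mean(x),
        sem = stats::sd(x) / sqrt(length(x)), n = length(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
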