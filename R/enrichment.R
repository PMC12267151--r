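#' Enrichment curve
#'
#' Container for one animal x analyte enrichment (or concentration) time
#' series. Times are minutes relative to the oral bolus; the basal sample is
#' taken before the bolus (by convention at -15 min) and anchors baseline
#' correction. Units are percent-scale for tracer enrichments (MPE for
#' molecular species measured by GC-MS, APE for CO2 carbon measured by IRMS)
#' or mmol/L for sugar concentrations.
#'
#' @param time_min numeric, strictly increasing sampling times (min).
#' @param value numeric enrichment/concentration at each time.
#' @param animal_id,analyte identifiers carried through the pipeline.
#' @param unit one of `"MPE"`, `"APE"`, `"mmol/L"`.
#' @param basal_time time of the pre-bolus basal sample (default -15 min).
#' @return An object of class `enrichment_curve`: a data frame with columns
#'   `time_min` and `value` plus identity attributes.
#' @export
enrichment_curve <- function(time_min, value, animal_id = NA_character_,
                             analyte = NA_character_, unit = c("MPE", "APE", "mmol/L"),
                             basal_time = -15) {
  unit <- match.arg(unit)
  stopifnot(length(time_min) == length(value), is.numeric(time_min), is.numeric(value))
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("time_min must be strictly increasing")
  }
  out <- data.frame(time_min = as.numeric(time_min), value = as.numeric(value))
  structure(out,
            class = c("enrichment_curve", "data.frame"),
            animal_id = animal_id, analyte = analyte, unit = unit,
            basal_time = basal_time, baseline_corrected = FALSE)
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("<enrichment_curve> %s / %s [%s], %d points%s\n",
              attr(x, "animal_id"), attr(x, "analyte"), attr(x, "unit"),
              nrow(x),
              if (isTRUE(attr(x, "baseline_corrected"))) ", baseline-corrected" else ""))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Fit a linear isotopologue-ratio calibration
#'
#' Ordinary least-squares line mapping a measured isotopologue peak-area
#' ratio (e.g. m+4/m+0 for a uniformly labelled amino acid fragment) to
#' known standard enrichments in molar percent excess (MPE). An intercept is
#' included so that the natural-abundance offset of the unspiked standard is
#' absorbed rather than forced through the origin.
#'
#' @param standards data frame with columns `known_mpe` and `measured_ratio`
#'   (or two numeric vectors via `known_mpe`/`measured_ratio`).
#' @param known_mpe,measured_ratio numeric vectors, used when `standards` is
#'   missing.
#' @return `calibration_model` with slope (MPE per unit ratio), intercept,
#'   `valid_range` (span of the standards in MPE), `residual_sd`, standard
#'   errors, and `n_standards`.
#' @export
build_calibration <- function(standards = NULL, known_mpe = NULL, measured_ratio = NULL) {
  if (!is.null(standards)) {
    stopifnot(is.data.frame(standards),
              all(c("known_mpe", "measured_ratio") %in% names(standards)))
    known_mpe <- standards$known_mpe
    measured_ratio <- standards$measured_ratio
  }
  stopifnot(is.numeric(known_mpe), is.numeric(measured_ratio),
            length(known_mpe) == length(measured_ratio))
  keep <- is.finite(known_mpe) & is.finite(measured_ratio)
  known_mpe <- known_mpe[keep]; measured_ratio <- measured_ratio[keep]
  if (length(unique(known_mpe)) < 2L) {
    stop("degenerate calibration: need at least 2 distinct standard enrichments")
  }
  if (any(known_mpe < 0)) stop("standard enrichments must be >= 0 MPE")
  fit <- stats::lm(known_mpe ~ measured_ratio)
  co <- stats::coef(fit)
  slope <- unname(co[["measured_ratio"]]); intercept <- unname(co[[1L]])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration failure: fitted slope is not positive")
  }
  sm <- summary(fit)
  structure(list(slope = slope, intercept = intercept,
                 valid_range = range(known_mpe),
                 residual_sd = sm$sigma,
                 slope_se = unname(sm$coefficients["measured_ratio", "Std. Error"]),
                 n_standards = length(known_mpe)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> MPE = %.6g * ratio + %.6g  (n = %d, residual SD %.3g MPE, valid %.3g-%.3g MPE)\n",
              x$slope, x$intercept, x$n_standards, x$residual_sd,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Convert isotopologue ratios to MPE
#'
#' Applies a fitted calibration line to measured peak-area ratios. Predicted
#' enrichments outside the standard range are flagged `extrapolated` but not
#' rejected; predictions below `-residual_sd` (beyond what calibration noise
#' explains) are clamped to 0 MPE and flagged `clamped`.
#'
#' @param ratio numeric vector of measured peak-area ratios (>= 0).
#' @param cal a `calibration_model` from [build_calibration()].
#' @return data frame with columns `ratio`, `mpe`, `extrapolated`, `clamped`.
#' @export
ratio_to_mpe <- function(ratio, cal) {
  stopifnot(inherits(cal, "calibration_model"), is.numeric(ratio))
  if (any(ratio < 0, na.rm = TRUE)) stop("peak-area ratios must be >= 0")
  mpe <- cal$slope * ratio + cal$intercept
  extrapolated <- mpe < cal$valid_range[1] | mpe > cal$valid_range[2]
  clamped <- mpe < -cal$residual_sd
  if (any(clamped, na.rm = TRUE)) {
    warning(sprintf("%d predicted enrichment(s) below -residual_sd clamped to 0 MPE",
                    sum(clamped, na.rm = TRUE)))
    mpe[which(clamped)] <- 0
  }
  data.frame(ratio = ratio, mpe = mpe,
             extrapolated = extrapolated, clamped = clamped)
}

#' Invert a calibration (MPE to expected ratio)
#'
#' Inverse of [ratio_to_mpe()]; used to simulate instrument ratios from known
#' enrichments and for round-trip checks.
#' @param mpe numeric enrichment in MPE.
#' @param cal a `calibration_model`.
#' @return expected peak-area ratio.
#' @export
mpe_to_ratio <- function(mpe, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  (mpe - cal$intercept) / cal$slope
}

#' Convert delta-13C values to atom percent excess
#'
#' Standard isotope-ratio arithmetic: a delta value (per mil vs VPDB) maps to
#' an isotope ratio R = R_std (delta/1000 + 1) and an atom fraction
#' AF = R/(1+R); APE is 100 times the atom-fraction difference between the
#' sample and its pre-bolus basal.
#'
#' @param delta_sample,delta_basal per-mil delta-13C values vs VPDB.
#' @param r_std 13C/12C ratio of the VPDB standard (default 0.0111802).
#' @return atom percent excess (APE), percent scale.
#' @export
delta_to_ape <- function(delta_sample, delta_basal, r_std = 0.0111802) {
  stopifnot(is.numeric(delta_sample), is.numeric(delta_basal), r_std > 0)
  if (any(!is.finite(delta_sample)) || any(!is.finite(delta_basal))) {
    stop("delta values must be finite")
  }
  if (any(delta_sample <= -1000) || any(delta_basal <= -1000)) {
    stop("delta <= -1000 per mil is nonphysical (implies ratio <= 0)")
  }
  af <- function(d) { r <- r_std * (d / 1000 + 1); r / (1 + r) }
  100 * (af(delta_sample) - af(delta_basal))
}

#' Baseline-correct an enrichment curve
#'
#' Subtracts the basal (pre-bolus) enrichment from every point so the basal
#' point is exactly zero. Negative post-correction values are retained — they
#' are unbiased measurement noise and dropping them would bias curve fits —
#' but are flagged. The operation is idempotent.
#'
#' @param curve an [enrichment_curve()] containing the basal time point.
#' @return the corrected `enrichment_curve`, with attribute `negative_flags`.
#' @export
baseline_correct <- function(curve) {
  stopifnot(inherits(curve, "enrichment_curve"))
  bt <- attr(curve, "basal_time")
  i <- which(curve$time_min == bt)
  if (length(i) != 1L) {
    stop(sprintf("missing basal point at t = %g min for animal '%s', analyte '%s'",
                 bt, attr(curve, "animal_id"), attr(curve, "analyte")))
  }
  basal <- curve$value[i]
  curve$value <- curve$value - basal
  attr(curve, "baseline_corrected") <- TRUE
  attr(curve, "negative_flags") <- curve$value < 0 & curve$time_min != bt
  curve
}

#' Post-bolus portion of a curve
#'
#' Drops the basal sample, returning only points at t > 0 (the fit and AUC
#' stages operate on the post-bolus grid).
#' @param curve an `enrichment_curve`.
#' @return data frame with `time_min`, `value`.
#' @export
post_bolus <- function(curve) {
  stopifnot(inherits(curve, "enrichment_curve"))
  as.data.frame(curve)[curve$time_min > 0, , drop = FALSE]
}
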