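#' Read and validate a long-format curve CSV
#'
#' Schema: `animal_id`, `analyte`, `time_min`, `measurement_type`
#' (`ratio`, `delta`, `enrichment`, `concentration`), `value`; optional
#' `unit` and `fragment_shift`. Validation is total before any computation:
#' a missing column aborts with its name; non-numeric or non-finite values
#' are reported per row.
#'
#' @param path CSV path (UTF-8, header required).
#' @return validated data frame.
#' @export
read_curves_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "analyte", "time_min", "measurement_type", "value")
  miss <- setdiff(need, names(dat))
  if (length(miss)) {
    stop("curves file '", basename(path), "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad_type <- !dat$measurement_type %in% c("ratio", "delta", "enrichment", "concentration")
  if (any(bad_type)) {
    stop(sum(bad_type), " row(s) with unknown measurement_type (first at row ",
         which(bad_type)[1], ")")
  }
  if (!is.numeric(dat$time_min) || !is.numeric(dat$value) ||
      any(!is.finite(dat$time_min)) || any(!is.finite(dat$value))) {
    stop("time_min and value must be finite numerics")
  }
  dat
}

#' Convert raw instrument rows to enrichment rows
#'
#' The enrich stage of the pipeline: `ratio` rows go through the analyte's
#' calibration line ([ratio_to_mpe()]); `delta` rows are converted to APE
#' against each animal x analyte basal delta ([delta_to_ape()], which is
#' baseline-referenced by construction, so the basal row becomes 0);
#' `enrichment` and `concentration` rows pass through unchanged.
#'
#' @param curves validated long table (see [read_curves_csv()]).
#' @param calibrations named list of [build_calibration()] models keyed by
#'   analyte; required if any `ratio` rows are present.
#' @param r_std VPDB 13C/12C ratio for delta conversion.
#' @param basal_time basal sample time (min).
#' @return long table with all rows on the enrichment/concentration scale.
#' @export
enrich_curves <- function(curves, calibrations = NULL, r_std = 0.0111802,
                          basal_time = -15) {
  out <- curves
  is_ratio <- out$measurement_type == "ratio"
  if (any(is_ratio)) {
    for (an in unique(out$analyte[is_ratio])) {
      cal <- calibrations[[an]]
      if (is.null(cal)) stop("no calibration model supplied for analyte '", an, "'")
      i <- which(is_ratio & out$analyte == an)
      out$value[i] <- ratio_to_mpe(out$value[i], cal)$mpe
      out$measurement_type[i] <- "enrichment"
      if ("unit" %in% names(out)) out$unit[i] <- "MPE"
    }
  }
  is_delta <- out$measurement_type == "delta"
  if (any(is_delta)) {
    keys <- unique(out[is_delta, c("animal_id", "analyte")])
    for (r in seq_len(nrow(keys))) {
      i <- which(is_delta & out$animal_id == keys$animal_id[r] &
                   out$analyte == keys$analyte[r])
      b <- out$value[i][out$time_min[i] == basal_time]
      if (length(b) != 1L) {
        stop("missing basal delta for animal '", keys$animal_id[r],
             "', analyte '", keys$analyte[r], "'")
      }
      out$value[i] <- delta_to_ape(out$value[i], b, r_std)
      out$measurement_type[i] <- "enrichment"
      if ("unit" %in% names(out)) out$unit[i] <- "APE"
    }
  }
  out
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the end-to-end pipeline
#'
#' simulate (or ingest) -> enrich -> fit -> metrics -> report. Writes
#' `animals.csv`, `weights.csv`, `curves.csv`, `truth.csv` (when
#' simulating), `fits.csv`, `kinetics.csv`, `sugar_summary.csv`,
#' `group_summary.csv` and a `manifest.json` recording the seed, a config
#' hash, per-file md5 checksums and row counts, the recovery mode and AUC
#' method. Deterministic stages reproduce identical checksums for identical
#' seed + config.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the simulation stage.
#' @param config a [sim_config()]; ignored when `input_curves` is given.
#' @param input_curves optional path to a curves CSV to analyze instead of
#'   simulating (metadata CSV may be supplied via `input_animals`).
#' @param input_animals optional path to an animal metadata CSV.
#' @param calibrations optional named calibration list for `ratio` rows.
#' @param rec_mode,auc_method,families passed to [analyze_cohort()].
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = sim_config(),
                         input_curves = NULL, input_animals = NULL,
                         calibrations = NULL,
                         rec_mode = c("dimensional", "literal"),
                         auc_method = c("model", "trapezoid"),
                         families = c("bateman", "lognormal_peak", "gamma_variate")) {
  rec_mode <- match.arg(rec_mode)
  auc_method <- match.arg(auc_method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  if (is.null(input_curves)) {
    cohort <- simulate_cohort(config, seed = seed)
    animals <- cohort$animals
    curves <- cohort$curves
    files["animals"] <- .write_csv(animals, file.path(out_dir, "animals.csv"))
    files["weights"] <- .write_csv(cohort$weights, file.path(out_dir, "weights.csv"))
    files["curves"] <- .write_csv(curves, file.path(out_dir, "curves.csv"))
    files["truth"] <- .write_csv(cohort$truth, file.path(out_dir, "truth.csv"))
  } else {
    curves <- read_curves_csv(input_curves)
    curves <- enrich_curves(curves, calibrations)
    animals <- if (!is.null(input_animals)) {
      utils::read.csv(input_animals, stringsAsFactors = FALSE)
    } else NULL
    files["curves"] <- .write_csv(curves, file.path(out_dir, "curves.csv"))
  }

  res <- analyze_cohort(curves, doses = config$doses, rec_mode = rec_mode,
                        auc_method = auc_method, families = families,
                        r_co2 = config$r_co2,
                        normalization = config$normalization,
                        basal_time = config$basal_time)
  if (!is.null(res$fits)) {
    files["fits"] <- .write_csv(res$fits, file.path(out_dir, "fits.csv"))
  }
  files["kinetics"] <- .write_csv(res$kinetics, file.path(out_dir, "kinetics.csv"))
  if (!is.null(res$sugars)) {
    files["sugars"] <- .write_csv(res$sugars, file.path(out_dir, "sugar_summary.csv"))
  }
  if (!is.null(animals)) {
    gs <- group_summary(res$kinetics, animals)
    files["group_summary"] <- .write_csv(gs, file.path(out_dir, "group_summary.csv"))
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config_as_list(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["config"] <- cfg_path
  sums <- tools::md5sum(unname(files))
  manifest <- list(
    package = "tracerkin",
    version = as.character(utils::packageVersion("tracerkin")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    rec_mode = rec_mode,
    auc_method = auc_method,
    simulated = is.null(input_curves),
    files = lapply(stats::setNames(names(files), names(files)), function(k) {
      list(path = basename(files[[k]]), md5 = unname(sums[[files[[k]]]]),
           rows = tryCatch(nrow(utils::read.csv(files[[k]])), error = function(e) NA))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# serialize a sim_config to plain lists for hashing/JSON
config_as_list <- function(cfg) {
  x <- unclass(cfg)
  x$group_means <- as.list(x$group_means)
  x$doses <- lapply(x$doses, unclass)
  x$group_sizes <- as.list(x$group_sizes)
  x$normalization <- as.list(x$normalization)
  x
}
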