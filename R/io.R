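#' @title Reading and writing analysis tables
#' @description All tables round-trip through plain CSV.  Writers use a
#'   fixed format (no row names, `NA` for missing), so a rerun with the
#'   same seed and configuration produces byte-identical files.  Column
#'   schemas are documented in `system.file("extdata", "schemas.csv",
#'   package = "hdps")`.
#' @name hdps_io
NULL

write_csv_fixed <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, na = "NA",
                   fileEncoding = "UTF-8", eol = "\n")
}

#' Write a synthetic dataset to CSV files
#'
#' @param sim an `hdps_sim` object from [simulate_hdps_data()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "hdps_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(cohort = file.path(dir, "cohort.csv"),
             events = file.path(dir, "events.csv"),
             map_observation = file.path(dir, "map_observation.csv"),
             map_prescription = file.path(dir, "map_prescription.csv"),
             map_prescription_fallback =
               file.path(dir, "map_prescription_fallback.csv"),
             exclusions = file.path(dir, "exclusions.csv"))
  write_csv_fixed(sim$cohort, files["cohort"])
  write_csv_fixed(sim$events, files["events"])
  write_csv_fixed(sim$maps$observation, files["map_observation"])
  write_csv_fixed(sim$maps$prescription, files["map_prescription"])
  write_csv_fixed(sim$maps$prescription_fallback,
                  files["map_prescription_fallback"])
  write_csv_fixed(data.frame(code = sim$maps$exclusions),
                  files["exclusions"])
  invisible(files)
}

cohort_factor_levels <- function() {
  list(age_group = c("35-54", "55-64", "65-74", "75+"),
       bmi_cat = c("underweight", "normal", "overweight", "obese"),
       ethnicity = c("White", "South Asian", "Black", "Mixed", "Unknown"),
       imd_quintile = as.character(1:5),
       exacerb_cat = c("0", "1", "2+"))
}

#' Read a patient cohort table
#'
#' @param path CSV written by [write_sim_data()] (or matching its
#'   schema).
#' @return Data frame with categorical columns restored as factors.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(cohort_factor_levels())) {
    if (nm %in% names(x))
      x[[nm]] <- factor(x[[nm]], levels = cohort_factor_levels()[[nm]])
  }
  x
}

#' Read a long code-event table
#' @param path CSV with columns patient_id, dimension, raw_code,
#'   event_date.
#' @return Data frame.
#' @export
read_code_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "integer",
                                 dimension = "character",
                                 raw_code = "character",
                                 event_date = "integer"))
}

#' Read a two-column code-mapping table
#' @param path CSV with columns source_code, target_code.
#' @return Data frame.
#' @export
read_mapping_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(source_code = "character",
                                 target_code = "character"))
}

#' Write the result tables of a fitted analysis
#'
#' Persists the tidy effect estimates, the balance table, the covariate
#' scores (the role of the published "top 30 ranked covariates" tables),
#' the unmapped-code report (top 100), weight diagnostics and the
#' filter-count log.  Output is deterministic given the fit.
#'
#' @param fit an `hdps_fit` object.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_hdps_results <- function(fit, dir) {
  stopifnot(inherits(fit, "hdps_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(estimates = file.path(dir, "estimates.csv"),
             balance = file.path(dir, "balance.csv"),
             scores = file.path(dir, "scores.csv"),
             unmapped = file.path(dir, "unmapped_top100.csv"),
             diagnostics = file.path(dir, "diagnostics.csv"),
             filter_log = file.path(dir, "filter_log.csv"))
  write_csv_fixed(effect_estimates(fit), files["estimates"])
  write_csv_fixed(fit$balance, files["balance"])
  sc <- fit$scores[order(fit$scores$rank, na.last = TRUE), ]
  write_csv_fixed(sc, files["scores"])
  write_csv_fixed(utils::head(fit$unmapped, 100L), files["unmapped"])
  diag <- fit$conventional$diagnostics
  if (!is.null(fit$hdps)) diag <- rbind(diag, fit$hdps$diagnostics)
  write_csv_fixed(diag, files["diagnostics"])
  ns <- fit$ns
  write_csv_fixed(data.frame(stage = names(ns),
                             n = unlist(ns, use.names = FALSE)),
                  files["filter_log"])
  invisible(files)
}
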