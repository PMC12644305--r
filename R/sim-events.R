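#' Code registry for the synthetic generator
#'
#' Enumerates every harmonized code the generator can emit, with its care
#' dimension and role.  Confounder-proxy codes fire through a threshold
#' logistic in one latent variable (cut points spread over the latent's
#' quantiles, so the set of indicators forms a step-function basis for the
#' latent); instrument codes fire on treatment-arm membership only; noise
#' codes fire at a fixed prevalence independently of everything; exposure-
#' and outcome-defining codes exist so that the analysis-side exclusions
#' have something real to remove.
#'
#' @param config a [sim_config()] object.
#' @return Data frame with columns `dimension`, `harmonized`, `role`
#'   (confounder / instrument / noise / exposure_class / outcome_class),
#'   `latent` (severity / frailty / NA), `cut`, `p_noise`, `p0`, `p1`.
#' @export
make_code_registry <- function(config) {
  config <- validate_sim_config(config)
  dims <- c("observation", "prescription", "hospitalisation")
  n_sev <- ceiling(config$n_confounder_codes / 2)
  n_fra <- config$n_confounder_codes - n_sev

  conf_letter <- c(observation = "S", prescription = NA,
                   hospitalisation = "H")
  fra_letter <- c(observation = "F", prescription = NA,
                  hospitalisation = "K")
  inst_letter <- c(observation = "I", prescription = NA,
                   hospitalisation = "V")
  noise_letter <- c(observation = "N", prescription = NA,
                    hospitalisation = "Z")

  code_name <- function(dim, role, latent, i) {
    if (dim == "prescription") {
      stem <- switch(role,
                     confounder = if (latent == "severity") "0201" else "0202",
                     instrument = "0401",
                     noise = "0901")
      sprintf("%s%02d", stem, i)
    } else {
      letter <- switch(role,
                       confounder = if (latent == "severity")
                         conf_letter[[dim]] else fra_letter[[dim]],
                       instrument = inst_letter[[dim]],
                       noise = noise_letter[[dim]])
      sprintf("%s%02d", letter, i)
    }
  }

  rows <- list()
  for (d in dims) {
    if (n_sev > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = d, role = "confounder", latent = "severity",
        harmonized = vapply(seq_len(n_sev), function(i)
          code_name(d, "confounder", "severity", i), ""),
        stringsAsFactors = FALSE)
    if (n_fra > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = d, role = "confounder", latent = "frailty",
        harmonized = vapply(seq_len(n_fra), function(i)
          code_name(d, "confounder", "frailty", i), ""),
        stringsAsFactors = FALSE)
    if (config$n_instrument_codes > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = d, role = "instrument", latent = NA_character_,
        harmonized = vapply(seq_len(config$n_instrument_codes), function(i)
          code_name(d, "instrument", NA, i), ""),
        stringsAsFactors = FALSE)
    if (config$n_noise_codes > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = d, role = "noise", latent = NA_character_,
        harmonized = vapply(seq_len(config$n_noise_codes), function(i)
          code_name(d, "noise", NA, i), ""),
        stringsAsFactors = FALSE)
  }
  # exposure-defining drug classes and the outcome ICD chapter
  rows[[length(rows) + 1L]] <- data.frame(
    dimension = "prescription", role = "exposure_class",
    latent = NA_character_, harmonized = c("030200", "030101", "030102"),
    stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    dimension = "hospitalisation", role = "outcome_class",
    latent = NA_character_, harmonized = "U07", stringsAsFactors = FALSE)

  reg <- do.call(rbind, rows)
  reg$cut <- NA_real_
  reg$p_noise <- NA_real_
  reg$p0 <- NA_real_
  reg$p1 <- NA_real_

  # spread confounder cut points over each latent's quantiles; mostly
  # above the median, as EHR proxy codes are mostly low-prevalence
  for (lv in c("severity", "frailty")) {
    idx <- which(reg$role == "confounder" & reg$latent == lv)
    if (length(idx))
      reg$cut[idx] <- stats::qnorm(seq(0.20, 0.95, length.out = length(idx)))
  }
  nidx <- which(reg$role == "noise")
  if (length(nidx))
    reg$p_noise[nidx] <- rep_len(seq(0.03, 0.25,
                                     length.out = max(config$n_noise_codes, 1)),
                                 length(nidx))
  iidx <- which(reg$role == "instrument")
  reg$p0[iidx] <- 0.30
  reg$p1[iidx] <- 0.96
  rownames(reg) <- NULL
  reg
}

# Raw-code aliases for one registry row (many-to-one onto the harmonized
# code); hospitalisation raws are ICD-like 4-character codes handled by
# truncation alone.
raw_aliases <- function(dimension, harmonized) {
  switch(dimension,
         observation = paste0("SNO", harmonized, c("a", "b")),
         prescription = paste0("DMD", harmonized, c("a", "b")),
         hospitalisation = paste0(harmonized, c("1", "9")))
}

#' Emit synthetic code events for a cohort
#'
#' Generates the long event stream the covariate-construction stage
#' consumes.  Confounder-proxy codes fire with probability increasing in
#' their latent variable and, once fired, produce a per-patient occurrence
#' count on `{1..10}` whose distribution also shifts with the latent, so
#' the once / sporadic / frequent recurrence levels carry signal.
#' Instrument codes fire on arm membership only; noise codes fire at fixed
#' prevalence.  Each occurrence gets a raw-code alias (several raw codes
#' per harmonized code) and an event date in days before the index date,
#' uniform on 1..400, so some events predate the 365-day assessment window.
#'
#' @param cohort output of [generate_cohort()].
#' @param config the same [sim_config()] used to generate the cohort.
#' @return Data frame with columns `patient_id`, `dimension`, `raw_code`,
#'   `event_date` (integer days before index, >= 1).
#' @export
emit_code_events <- function(cohort, config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 1L)
  reg <- make_code_registry(config)
  n <- nrow(cohort)
  sev <- cohort$latent_severity
  fra <- cohort$latent_frailty

  pid <- list(); raw <- list(); dim_out <- list(); cnt_latent <- list()
  for (r in seq_len(nrow(reg))) {
    role <- reg$role[r]
    p <- switch(role,
      confounder = {
        lat <- if (reg$latent[r] == "severity") sev else fra
        stats::plogis(config$proxy_slope * (lat - reg$cut[r]))
      },
      instrument = ifelse(cohort$exposure == 1L, reg$p1[r], reg$p0[r]),
      noise = rep(reg$p_noise[r], n),
      exposure_class = switch(reg$harmonized[r],
        "030200" = ifelse(cohort$exposure == 1L, 0.95, 0.005),
        "030101" = rep(0.95, n),
        "030102" = ifelse(cohort$exposure == 1L,
                          ifelse(cohort$triple_therapy == 1L, 0.95, 0.02),
                          0.95)),
      outcome_class = ifelse(cohort$event == 1L, 0.8, 0.02))
    fired <- which(stats::runif(n) < p)
    if (!length(fired)) next
    counts <- switch(role,
      confounder = {
        lat <- if (reg$latent[r] == "severity") sev else fra
        1L + stats::rbinom(length(fired), 9L,
                           stats::plogis(-1.8 + 0.9 * lat[fired]))
      },
      instrument = 1L + stats::rbinom(length(fired), 9L, 0.18),
      noise = 1L + stats::rbinom(length(fired), 9L, 0.15),
      exposure_class = 1L + stats::rbinom(length(fired), 9L, 0.30),
      outcome_class = rep(1L, length(fired)))
    pid[[r]] <- rep.int(fired, counts)
    k <- sum(counts)
    aliases <- raw_aliases(reg$dimension[r], reg$harmonized[r])
    raw[[r]] <- aliases[sample.int(length(aliases), k, replace = TRUE)]
    dim_out[[r]] <- rep.int(reg$dimension[r], k)
  }
  events <- data.frame(
    patient_id = unlist(pid, use.names = FALSE),
    dimension = unlist(dim_out, use.names = FALSE),
    raw_code = unlist(raw, use.names = FALSE),
    event_date = sample.int(400L, length(unlist(pid, use.names = FALSE)),
                            replace = TRUE),
    stringsAsFactors = FALSE
  )
  events
}

#' Build toy code-mapping tables
#'
#' Constructs the raw-to-harmonized mapping tables the mapping stage
#' consumes: an observation table (raw clinical codes to 4-character
#' ICD-like targets, truncated downstream to 3), a primary prescription
#' table (raw drug codes to 6-character formulary paragraphs) and a
#' fallback prescription table (8-character chapter strings of which the
#' first 6 characters are used).  Every fifth prescription code is placed
#' only in the fallback table to exercise that path.  A configurable
#' fraction of raw codes is deliberately omitted from the tables
#' (`round(fraction_unmapped * n_raw)` per table); exposure- and
#' outcome-defining codes are always mapped.
#'
#' @param config a [sim_config()] object.
#' @return List with elements `observation`, `prescription`,
#'   `prescription_fallback` (two-column data frames `source_code`,
#'   `target_code`) and `exclusions` (harmonized codes defining exposure
#'   and outcome, to be removed from the candidate pool).
#' @export
make_mapping_tables <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 2L)
  reg <- make_code_registry(config)

  obs <- reg[reg$dimension == "observation", ]
  obs_map <- data.frame(
    source_code = unlist(lapply(obs$harmonized, raw_aliases,
                                dimension = "observation")),
    target_code = rep(paste0(obs$harmonized, "9"), each = 2L),
    stringsAsFactors = FALSE)

  rx <- reg[reg$dimension == "prescription", ]
  protected <- rx$role %in% c("exposure_class", "outcome_class")
  fb_code <- !protected & (seq_len(nrow(rx)) %% 5L == 0L)
  rx_primary <- rx[!fb_code, ]
  rx_fb <- rx[fb_code, ]
  rx_map <- data.frame(
    source_code = unlist(lapply(rx_primary$harmonized, raw_aliases,
                                dimension = "prescription")),
    target_code = rep(rx_primary$harmonized, each = 2L),
    stringsAsFactors = FALSE)
  fb_map <- if (nrow(rx_fb)) data.frame(
    source_code = unlist(lapply(rx_fb$harmonized, raw_aliases,
                                dimension = "prescription")),
    target_code = rep(paste0(rx_fb$harmonized, "00"), each = 2L),
    stringsAsFactors = FALSE)
  else data.frame(source_code = character(), target_code = character(),
                  stringsAsFactors = FALSE)

  drop_fraction <- function(map, protected_codes) {
    droppable <- which(!map$source_code %in% protected_codes)
    n_drop <- round(config$fraction_unmapped * nrow(map))
    n_drop <- min(n_drop, length(droppable))
    if (n_drop > 0)
      map <- map[-sample(droppable, n_drop), , drop = FALSE]
    rownames(map) <- NULL
    map
  }
  protected_raws <- unlist(lapply(rx$harmonized[protected], raw_aliases,
                                  dimension = "prescription"))
  obs_map <- drop_fraction(obs_map, character())
  rx_map <- drop_fraction(rx_map, protected_raws)
  fb_map <- drop_fraction(fb_map, protected_raws)

  list(observation = obs_map,
       prescription = rx_map,
       prescription_fallback = fb_map,
       exclusions = c("030200", "030101", "030102", "U07"))
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_cohort()], [emit_code_events()]
#' and [make_mapping_tables()] under one configuration.
#'
#' @param config a [sim_config()] object.
#' @return List of class `hdps_sim` with elements `cohort`, `events`,
#'   `maps`, `code_info` (the generator's code registry, for verification
#'   only) and `config`.
#' @export
simulate_hdps_data <- function(config) {
  cohort <- generate_cohort(config)
  events <- emit_code_events(cohort, config)
  maps <- make_mapping_tables(config)
  out <- list(cohort = cohort, events = events, maps = maps,
              code_info = make_code_registry(config), config = config)
  class(out) <- "hdps_sim"
  out
}

#' @export
print.hdps_sim <- function(x, ...) {
  cat(sprintf("Synthetic HDPS dataset: %d patients, %d code events, %d codes\n",
              nrow(x$cohort), nrow(x$events), nrow(x$code_info)))
  cat(sprintf("  exposed: %d (%.1f%%), events: %d (%.2f%%)\n",
              sum(x$cohort$exposure), 100 * mean(x$cohort$exposure),
              sum(x$cohort$event), 100 * mean(x$cohort$event)))
  invisible(x)
}
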