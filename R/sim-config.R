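#' Simulation configuration for synthetic active-comparator cohorts
#'
#' Builds and validates the parameter set for the synthetic EHR generator.
#' The generator emulates a two-arm active-comparator COPD cohort followed
#' over a short pandemic window: confounding by indication operates partly
#' through latent severity and frailty variables that are withheld from the
#' analysis tables and are visible only through proxy codes emitted into
#' three care dimensions (primary-care observations, prescriptions,
#' hospitalisations).
#'
#' @param n_patients number of patients to simulate.
#' @param p_exposed_target target marginal probability of exposure (arm 1).
#'   The exposure-model intercept is calibrated numerically so the realised
#'   prevalence matches this target.
#' @param n_confounder_codes number of latent-proxy codes per dimension
#'   (split between severity and frailty proxies).
#' @param n_instrument_codes number of instrument-like codes per dimension;
#'   these fire on treatment-arm membership only (codes tied to the
#'   treatment pathway itself) and carry no outcome association.
#' @param n_noise_codes number of codes per dimension that fire
#'   independently of everything.
#' @param latent_effects list with elements `severity` and `frailty`, each
#'   a numeric vector `c(exposure = , outcome = )` giving the log-odds of
#'   exposure and log-hazard of outcome per unit of the standard-normal
#'   latent variable.
#' @param true_log_hr true conditional log hazard ratio of exposure on the
#'   outcome (0 = null).
#' @param target_event_risk target marginal cumulative event risk over the
#'   follow-up window; used to calibrate the baseline hazard when
#'   `baseline_hazard` is `NULL`.
#' @param baseline_hazard events per person-day at covariate reference
#'   values, or `NULL` to calibrate from `target_event_risk`.
#' @param followup_days administrative end of follow-up, in days after the
#'   index date.
#' @param censor_rate probability of independent random censoring before
#'   `followup_days`.
#' @param p_triple_given_exposed baseline probability that an exposed
#'   patient is on triple therapy; increases with latent severity.
#' @param proxy_slope slope of the threshold-logistic linking a latent
#'   variable to the firing probability of each of its proxy codes.
#' @param fraction_unmapped fraction of raw observation/prescription codes
#'   deliberately left out of the mapping tables, to exercise the
#'   unmapped-code reporting path.
#' @param missing_rates named numeric vector with elements `bmi`,
#'   `ethnicity`, `imd`: probabilities of a missing value in the
#'   corresponding cohort field.
#' @param covariate_effects_exposure,covariate_effects_outcome optional
#'   named numeric vectors overriding the built-in log-odds / log-hazard
#'   effects of the prespecified covariates (names must match columns of
#'   the prespecified design, see [prespecified_covariates()]).
#' @param seed integer seed; identical seeds give byte-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [emit_code_events()],
#'   [make_mapping_tables()], [simulate_hdps_data()]
#' @export
sim_config <- function(n_patients = 20000,
                       p_exposed_target = 0.4,
                       n_confounder_codes = 20,
                       n_instrument_codes = 1,
                       n_noise_codes = 20,
                       latent_effects = list(
                         severity = c(exposure = 0.5, outcome = 0.8),
                         frailty  = c(exposure = 0.25, outcome = 0.6)
                       ),
                       true_log_hr = 0,
                       target_event_risk = 0.01,
                       baseline_hazard = NULL,
                       followup_days = 184,
                       censor_rate = 0.05,
                       p_triple_given_exposed = 0.5,
                       proxy_slope = 4,
                       fraction_unmapped = 0.05,
                       missing_rates = c(bmi = 0.007, ethnicity = 0.099,
                                         imd = 0.0005),
                       covariate_effects_exposure = NULL,
                       covariate_effects_outcome = NULL,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    p_exposed_target = p_exposed_target,
    n_confounder_codes = as.integer(n_confounder_codes),
    n_instrument_codes = as.integer(n_instrument_codes),
    n_noise_codes = as.integer(n_noise_codes),
    latent_effects = latent_effects,
    true_log_hr = true_log_hr,
    target_event_risk = target_event_risk,
    baseline_hazard = baseline_hazard,
    followup_days = as.numeric(followup_days),
    censor_rate = censor_rate,
    p_triple_given_exposed = p_triple_given_exposed,
    proxy_slope = proxy_slope,
    fraction_unmapped = fraction_unmapped,
    missing_rates = missing_rates,
    covariate_effects_exposure = covariate_effects_exposure,
    covariate_effects_outcome = covariate_effects_outcome,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
      stop(sprintf("'%s' must be a probability in (0, 1)", nm), call. = FALSE)
  }
  chk_count <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0)
      stop(sprintf("'%s' must be a non-negative count", nm), call. = FALSE)
  }
  if (cfg$n_patients < 1L) stop("'n_patients' must be positive", call. = FALSE)
  chk_prob(cfg$p_exposed_target, "p_exposed_target")
  chk_prob(cfg$target_event_risk, "target_event_risk")
  chk_prob(cfg$censor_rate, "censor_rate")
  chk_prob(cfg$p_triple_given_exposed, "p_triple_given_exposed")
  chk_count(cfg$n_confounder_codes, "n_confounder_codes")
  chk_count(cfg$n_instrument_codes, "n_instrument_codes")
  chk_count(cfg$n_noise_codes, "n_noise_codes")
  if (cfg$followup_days <= 0)
    stop("'followup_days' must be positive", call. = FALSE)
  if (!is.null(cfg$baseline_hazard) &&
      (!is.finite(cfg$baseline_hazard) || cfg$baseline_hazard <= 0))
    stop("'baseline_hazard' must be a positive finite rate", call. = FALSE)
  if (!is.finite(cfg$true_log_hr))
    stop("'true_log_hr' must be finite", call. = FALSE)
  if (!is.finite(cfg$proxy_slope))
    stop("'proxy_slope' must be finite", call. = FALSE)
  if (cfg$fraction_unmapped < 0 || cfg$fraction_unmapped >= 1)
    stop("'fraction_unmapped' must be in [0, 1)", call. = FALSE)
  for (lv in c("severity", "frailty")) {
    eff <- cfg$latent_effects[[lv]]
    if (is.null(eff) || !all(c("exposure", "outcome") %in% names(eff)))
      stop(sprintf("latent_effects$%s must have 'exposure' and 'outcome' entries",
                   lv), call. = FALSE)
    if (any(!is.finite(eff)))
      stop(sprintf("latent_effects$%s contains non-finite values", lv),
           call. = FALSE)
  }
  for (nm in c("covariate_effects_exposure", "covariate_effects_outcome")) {
    eff <- cfg[[nm]]
    if (!is.null(eff) && any(!is.finite(eff)))
      stop(sprintf("'%s' contains non-finite values", nm), call. = FALSE)
  }
  mr <- cfg$missing_rates
  if (!all(c("bmi", "ethnicity", "imd") %in% names(mr)) ||
      any(!is.finite(mr)) || any(mr < 0) || any(mr >= 1))
    stop("'missing_rates' must name bmi/ethnicity/imd rates in [0, 1)",
         call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  patients: %d, target exposure prevalence: %.2f\n",
              x$n_patients, x$p_exposed_target))
  cat(sprintf("  follow-up: %g days, target event risk: %.3f, censor rate: %.2f\n",
              x$followup_days, x$target_event_risk, x$censor_rate))
  cat(sprintf("  codes per dimension: %d confounder-proxy, %d instrument, %d noise\n",
              x$n_confounder_codes, x$n_instrument_codes, x$n_noise_codes))
  cat(sprintf("  latent effects (exposure/outcome): severity %.2f/%.2f, frailty %.2f/%.2f\n",
              x$latent_effects$severity["exposure"],
              x$latent_effects$severity["outcome"],
              x$latent_effects$frailty["exposure"],
              x$latent_effects$frailty["outcome"]))
  cat(sprintf("  true conditional log HR: %g, seed: %d\n", x$true_log_hr, x$seed))
  invisible(x)
}
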