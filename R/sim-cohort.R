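#' Names of the prespecified cohort covariates
#'
#' The investigator-specified confounder set used in the conventional
#' propensity score: demographic, lifestyle and comorbidity variables
#' defined at the index date, plus vaccination history and a categorised
#' count of recent disease exacerbations as a severity marker.
#'
#' @return Character vector of column names in the cohort table.
#' @export
prespecified_covariate_names <- function() {
  c("age_group", "gender_female", "bmi_cat", "smoking_former", "ethnicity",
    "imd_quintile", "cancer", "diabetes", "ckd", "cvd", "hypertension",
    "past_asthma", "immunosuppression", "flu_vaccine", "pneumo_vaccine",
    "exacerb_cat")
}

# Dummy-coded design matrix (no intercept column) over the prespecified
# covariates; factor levels are fixed so column names are stable.
prespec_design <- function(cohort) {
  ff <- stats::as.formula(paste("~", paste(prespecified_covariate_names(),
                                           collapse = " + ")))
  mm <- stats::model.matrix(ff, data = cohort)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

# Built-in covariate effects, keyed by dummy-column name; anything not
# named has effect zero.
default_exposure_effects <- function() {
  c(past_asthma = 1.1, exacerb_cat1 = 0.35, `exacerb_cat2+` = 0.7,
    pneumo_vaccine = -0.35, smoking_former = 0.2, flu_vaccine = -0.2,
    gender_female = 0.06)
}

default_outcome_effects <- function() {
  c(`age_group55-64` = 0.4, `age_group65-74` = 0.8, `age_group75+` = 1.3,
    gender_female = -0.3, cvd = 0.3, diabetes = 0.2, ckd = 0.3,
    immunosuppression = 0.5, `exacerb_cat2+` = 0.4, hypertension = 0.1)
}

# Expand a named effect specification to the full dummy-column set.
expand_effects <- function(spec, cols, defaults) {
  out <- stats::setNames(numeric(length(cols)), cols)
  if (is.null(spec)) spec <- defaults
  if (length(spec) == 1L && is.null(names(spec))) {
    out[] <- spec
    return(out)
  }
  bad <- setdiff(names(spec), cols)
  if (length(bad))
    stop("unknown covariate effect name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out[names(spec)] <- spec
  out
}

#' Generate a synthetic active-comparator cohort
#'
#' Simulates one patient table: prespecified covariates with realistic
#' prevalences, standard-normal latent severity and frailty, an exposure
#' assignment whose log-odds depend on prespecified covariates and the
#' latents (intercept calibrated to the target prevalence), a triple-therapy
#' flag among the exposed (probability increasing in severity), and an
#' exponential survival outcome with log-linear hazard, administrative
#' censoring at the end of follow-up and independent random censoring.
#' Event times are rounded up to whole days, so ties occur.
#'
#' The latent columns (`latent_severity`, `latent_frailty`) are carried for
#' verification only and must never enter estimation; [hdps_fit()] ignores
#' them by construction.
#'
#' @param config a [sim_config()] object.
#' @return A data frame with one row per patient: `patient_id`, `exposure`,
#'   the prespecified covariates, `latent_severity`, `latent_frailty`,
#'   `triple_therapy`, `time_to_event` (days, in `1..followup_days`) and
#'   `event` (0/1).
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients

  cohort <- data.frame(
    patient_id = seq_len(n),
    age_group = factor(sample(c("35-54", "55-64", "65-74", "75+"), n, TRUE,
                              c(0.12, 0.25, 0.35, 0.28)),
                       levels = c("35-54", "55-64", "65-74", "75+")),
    gender_female = stats::rbinom(n, 1L, 0.46),
    bmi_cat = factor(sample(c("underweight", "normal", "overweight", "obese"),
                            n, TRUE, c(0.05, 0.31, 0.32, 0.32)),
                     levels = c("underweight", "normal", "overweight",
                                "obese")),
    smoking_former = stats::rbinom(n, 1L, 0.57),
    ethnicity = factor(sample(c("White", "South Asian", "Black", "Mixed"),
                              n, TRUE, c(0.95, 0.03, 0.015, 0.005)),
                       levels = c("White", "South Asian", "Black", "Mixed")),
    imd_quintile = factor(sample(as.character(1:5), n, TRUE,
                                 c(0.13, 0.17, 0.18, 0.23, 0.29)),
                          levels = as.character(1:5)),
    cancer = stats::rbinom(n, 1L, 0.19),
    diabetes = stats::rbinom(n, 1L, 0.25),
    ckd = stats::rbinom(n, 1L, 0.30),
    cvd = stats::rbinom(n, 1L, 0.295),
    hypertension = stats::rbinom(n, 1L, 0.51),
    past_asthma = stats::rbinom(n, 1L, 0.17),
    immunosuppression = stats::rbinom(n, 1L, 0.012),
    flu_vaccine = stats::rbinom(n, 1L, 0.79),
    pneumo_vaccine = stats::rbinom(n, 1L, 0.12),
    exacerb_cat = factor(sample(c("0", "1", "2+"), n, TRUE,
                                c(0.62, 0.25, 0.13)),
                         levels = c("0", "1", "2+"))
  )
  cohort$latent_severity <- stats::rnorm(n)
  cohort$latent_frailty <- stats::rnorm(n)

  X <- prespec_design(cohort)
  beta_e <- expand_effects(config$covariate_effects_exposure, colnames(X),
                           default_exposure_effects())
  gamma_d <- expand_effects(config$covariate_effects_outcome, colnames(X),
                            default_outcome_effects())
  le <- config$latent_effects

  lp_e <- drop(X %*% beta_e) +
    cohort$latent_severity * le$severity[["exposure"]] +
    cohort$latent_frailty * le$frailty[["exposure"]]
  a0 <- stats::uniroot(function(a) mean(stats::plogis(a + lp_e)) -
                         config$p_exposed_target,
                       c(-25, 25), tol = 1e-10)$root
  cohort$exposure <- stats::rbinom(n, 1L, stats::plogis(a0 + lp_e))

  cohort$triple_therapy <- 0L
  exp_idx <- which(cohort$exposure == 1L)
  if (length(exp_idx)) {
    p_tri <- stats::plogis(stats::qlogis(config$p_triple_given_exposed) +
                             0.9 * cohort$latent_severity[exp_idx])
    cohort$triple_therapy[exp_idx] <- stats::rbinom(length(exp_idx), 1L, p_tri)
  }

  lp_d <- drop(X %*% gamma_d) +
    cohort$latent_severity * le$severity[["outcome"]] +
    cohort$latent_frailty * le$frailty[["outcome"]] +
    config$true_log_hr * cohort$exposure
  rel_haz <- exp(lp_d)
  fu <- config$followup_days
  if (is.null(config$baseline_hazard)) {
    log_h0 <- stats::uniroot(function(lh)
      mean(1 - exp(-exp(lh) * rel_haz * fu)) - config$target_event_risk,
      c(-30, 0), tol = 1e-12)$root
    h0 <- exp(log_h0)
  } else {
    h0 <- config$baseline_hazard
  }
  t_event <- stats::rexp(n, rate = h0 * rel_haz)
  cens_rate <- -log(1 - config$censor_rate) / fu
  t_cens <- stats::rexp(n, rate = cens_rate)
  t_obs <- pmin(t_event, t_cens, fu)
  cohort$event <- as.integer(t_event <= pmin(t_cens, fu))
  cohort$time_to_event <- pmax(1, ceiling(t_obs))

  # inject missingness (resolved later by apply_missing_data_rules())
  mr <- config$missing_rates
  if (mr[["bmi"]] > 0)
    cohort$bmi_cat[stats::runif(n) < mr[["bmi"]]] <- NA
  if (mr[["ethnicity"]] > 0)
    cohort$ethnicity[stats::runif(n) < mr[["ethnicity"]]] <- NA
  if (mr[["imd"]] > 0)
    cohort$imd_quintile[stats::runif(n) < mr[["imd"]]] <- NA

  attr(cohort, "baseline_hazard") <- h0
  attr(cohort, "exposure_intercept") <- a0
  cohort
}
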