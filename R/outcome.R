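#' @title Weighted outcome models
#' @description Exposure-effect estimators for the weighted, trimmed
#'   cohort: IPT-weighted Cox hazard ratios (Efron ties, robust sandwich
#'   variance), weighted logistic odds ratios, weighted risk differences,
#'   weighted Kaplan-Meier curves, and a Schoenfeld-residual
#'   proportional-hazards diagnostic.  All confidence intervals are
#'   Wald-type at the 95% level, formed on the log scale for ratio
#'   estimands.
#' @name outcome_models
NULL

new_effect_estimate <- function(estimand, log_point, se_log, k = NA_integer_,
                                cohort = NA_character_,
                                outcome = NA_character_, ratio = TRUE) {
  z <- stats::qnorm(0.975)
  if (ratio) {
    data.frame(estimand = estimand, point = exp(log_point),
               se = se_log, lower = exp(log_point - z * se_log),
               upper = exp(log_point + z * se_log),
               k = k, cohort = cohort, outcome = outcome,
               stringsAsFactors = FALSE)
  } else {
    data.frame(estimand = estimand, point = log_point, se = se_log,
               lower = log_point - z * se_log,
               upper = log_point + z * se_log,
               k = k, cohort = cohort, outcome = outcome,
               stringsAsFactors = FALSE)
  }
}

check_arms_have_events <- function(event, exposure, what) {
  if (sum(event[exposure == 1L]) == 0L || sum(event[exposure == 0L]) == 0L)
    stop(sprintf("inestimable %s: zero events in a treatment arm", what),
         call. = FALSE)
}

#' IPT-weighted Cox regression hazard ratio
#'
#' Fits a weighted Cox proportional-hazards model with exposure as the
#' only covariate, Efron handling of tied event times (day-resolution
#' follow-up produces ties) and a robust sandwich variance, as required
#' for weighted estimating equations.
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @param exposure 0/1 treatment indicator.
#' @param weights positive weights (default: all 1, giving the unweighted
#'   fit).
#' @param k,cohort,outcome labels carried into the estimate row.
#' @return List of class `hdps_effect`: `estimate` (one-row data frame:
#'   estimand `HR`, point, robust SE of the log HR, 95% CI) and `fit`
#'   (the underlying [survival::coxph()] object).
#' @export
weighted_cox_hr <- function(time, event, exposure, weights = NULL,
                            k = NA_integer_, cohort = NA_character_,
                            outcome = NA_character_) {
  stopifnot(all(time > 0))
  if (is.null(weights)) weights <- rep(1, length(time))
  stopifnot(all(weights > 0))
  check_arms_have_events(event, exposure, "HR")
  df <- data.frame(time = time, event = event, exposure = exposure,
                   w = weights)
  fit <- survival::coxph(survival::Surv(time, event) ~ exposure,
                         data = df, weights = w, ties = "efron",
                         robust = TRUE)
  b <- unname(fit$coefficients["exposure"])
  se <- sqrt(fit$var[1L, 1L])
  structure(list(estimate = new_effect_estimate("HR", b, se, k, cohort,
                                                outcome),
                 fit = fit),
            class = "hdps_effect")
}

#' @export
print.hdps_effect <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("%s %.3f (95%% CI %.3f-%.3f)\n", e$estimand, e$point,
              e$lower, e$upper))
  invisible(x)
}

#' IPT-weighted logistic regression odds ratio
#'
#' Weighted logistic score equations (quasibinomial fit, so non-integer
#' weights are handled) with a robust sandwich variance.
#'
#' @inheritParams weighted_cox_hr
#' @return List of class `hdps_effect` with estimand `OR`.
#' @export
weighted_logistic_or <- function(event, exposure, weights = NULL,
                                 k = NA_integer_, cohort = NA_character_,
                                 outcome = NA_character_) {
  if (is.null(weights)) weights <- rep(1, length(event))
  stopifnot(all(weights > 0))
  check_arms_have_events(event, exposure, "OR")
  df <- data.frame(event = event, exposure = exposure, w = weights)
  fit <- stats::glm(event ~ exposure, family = stats::quasibinomial(),
                    weights = w, data = df)
  if (!fit$converged || any(abs(stats::coef(fit)) > 15))
    stop("separation in the weighted logistic model", call. = FALSE)
  b <- unname(stats::coef(fit)["exposure"])
  vc <- sandwich::vcovHC(fit, type = "HC0")
  se <- sqrt(vc["exposure", "exposure"])
  structure(list(estimate = new_effect_estimate("OR", b, se, k, cohort,
                                                outcome),
                 fit = fit),
            class = "hdps_effect")
}

#' IPT-weighted risk difference
#'
#' `RD = weighted risk(exposed) - weighted risk(unexposed)`, with a
#' standard error from the influence function of the two weighted-mean
#' ratios (default) or a stratified nonparametric bootstrap.
#'
#' @inheritParams weighted_cox_hr
#' @param se_method `"influence"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates when `se_method = "bootstrap"`.
#' @return List of class `hdps_effect` with estimand `RD` (CI on the
#'   additive scale).
#' @export
weighted_risk_difference <- function(event, exposure, weights = NULL,
                                     se_method = c("influence", "bootstrap"),
                                     n_boot = 200,
                                     k = NA_integer_,
                                     cohort = NA_character_,
                                     outcome = NA_character_) {
  se_method <- match.arg(se_method)
  if (is.null(weights)) weights <- rep(1, length(event))
  stopifnot(all(weights > 0))
  e1 <- exposure == 1L; e0 <- exposure == 0L
  if (!any(e1) || !any(e0))
    stop("both treatment arms must be non-empty", call. = FALSE)

  risk <- function(sel, ev = event, w = weights)
    sum(w[sel] * ev[sel]) / sum(w[sel])
  r1 <- risk(e1); r0 <- risk(e0)
  rd <- r1 - r0

  if (se_method == "influence") {
    # ratio-estimator linearisation per arm; cross-terms vanish because a
    # patient contributes to exactly one arm
    a1 <- weights * exposure * event; b1 <- weights * exposure
    a0 <- weights * (1 - exposure) * event; b0 <- weights * (1 - exposure)
    v1 <- sum((a1 - r1 * b1)^2) / sum(b1)^2
    v0 <- sum((a0 - r0 * b0)^2) / sum(b0)^2
    se <- sqrt(v1 + v0)
  } else {
    idx1 <- which(e1); idx0 <- which(e0)
    reps <- vapply(seq_len(n_boot), function(i) {
      s1 <- sample(idx1, length(idx1), replace = TRUE)
      s0 <- sample(idx0, length(idx0), replace = TRUE)
      sum(weights[s1] * event[s1]) / sum(weights[s1]) -
        sum(weights[s0] * event[s0]) / sum(weights[s0])
    }, 0)
    se <- stats::sd(reps)
  }
  structure(list(estimate = new_effect_estimate("RD", rd, se, k, cohort,
                                                outcome, ratio = FALSE),
                 risks = c(exposed = r1, unexposed = r0)),
            class = "hdps_effect")
}

#' IPT-weighted Kaplan-Meier survival curves
#'
#' Weighted product-limit estimates per treatment arm.  Curves start at 1
#' and are non-increasing; a single event of weight `w` at time `t` drops
#' the curve by `w / (total weight at risk at t)` times the survival so
#' far.
#'
#' @inheritParams weighted_cox_hr
#' @return List of class `hdps_survfit`: `curves` (data frame `arm`,
#'   `time`, `surv`, `n_risk`) and `fit` (the [survival::survfit()]
#'   object).
#' @export
weighted_survival_curves <- function(time, event, exposure,
                                     weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(time))
  stopifnot(all(weights > 0), all(time > 0))
  df <- data.frame(time = time, event = event, exposure = exposure,
                   w = weights)
  fit <- survival::survfit(survival::Surv(time, event) ~ exposure,
                           data = df, weights = w)
  strata_lab <- if (is.null(fit$strata))
    rep(sprintf("exposure=%d", unique(df$exposure)), length(fit$time))
  else rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    arm = ifelse(grepl("exposure=1", strata_lab), "exposed", "unexposed"),
    time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
    stringsAsFactors = FALSE)
  structure(list(curves = curves, fit = fit), class = "hdps_survfit")
}

#' @export
print.hdps_survfit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Schoenfeld-residual proportional-hazards diagnostic
#'
#' Correlation test of the scaled Schoenfeld residuals against time, plus
#' the slope of a least-squares line through them.  Purely diagnostic:
#' under non-proportionality the hazard ratio is interpreted as an average
#' over the follow-up period, never re-estimated.
#'
#' @param cox_fit a [survival::coxph()] fit (e.g. `$fit` from
#'   [weighted_cox_hr()]).
#' @return List: `statistic`, `p_value`, `slope`, `insufficient_events`
#'   (TRUE when fewer than 2 events make the diagnostic undefined, in
#'   which case the other entries are `NA`).
#' @export
schoenfeld_ph_check <- function(cox_fit) {
  n_events <- sum(cox_fit$y[, ncol(cox_fit$y)])
  if (n_events < 2)
    return(list(statistic = NA_real_, p_value = NA_real_,
                slope = NA_real_, insufficient_events = TRUE))
  zph <- survival::cox.zph(cox_fit)
  sl <- unname(stats::coef(stats::lm(zph$y[, 1L] ~ zph$x))[2L])
  list(statistic = unname(zph$table[1L, "chisq"]),
       p_value = unname(zph$table[1L, "p"]),
       slope = sl,
       insufficient_events = FALSE)
}
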