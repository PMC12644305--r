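#' Resolve missing values under the analysis rules
#'
#' Missing BMI category is assigned to `"normal"` (extreme values are more
#' likely to be recorded, so the unrecorded cluster near the normal
#' range); missing ethnicity becomes its own `"Unknown"` level; patients
#' with missing deprivation quintile are excluded, as absence may indicate
#' poor-quality records.  Missingness in any other field is an error: no
#' rule covers it.
#'
#' @param cohort patient table with (possibly missing) `bmi_cat`,
#'   `ethnicity`, `imd_quintile` columns.
#' @return The cohort with missingness resolved; the number of dropped
#'   rows is recorded in `attr(, "n_imd_dropped")`.
#' @export
apply_missing_data_rules <- function(cohort) {
  if ("bmi_cat" %in% names(cohort))
    cohort$bmi_cat[is.na(cohort$bmi_cat)] <- "normal"
  if ("ethnicity" %in% names(cohort)) {
    eth <- as.character(cohort$ethnicity)
    eth[is.na(eth)] <- "Unknown"
    lv <- unique(c(levels(cohort$ethnicity), "Unknown"))
    cohort$ethnicity <- factor(eth, levels = lv)
  }
  n_dropped <- 0L
  if ("imd_quintile" %in% names(cohort)) {
    miss <- is.na(cohort$imd_quintile)
    n_dropped <- sum(miss)
    cohort <- cohort[!miss, , drop = FALSE]
  }
  other <- setdiff(names(cohort), c("bmi_cat", "ethnicity", "imd_quintile"))
  bad <- other[vapply(cohort[other], anyNA, TRUE)]
  if (length(bad))
    stop("missing values in field(s) not covered by the missing-data rules: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rownames(cohort) <- NULL
  attr(cohort, "n_imd_dropped") <- n_dropped
  cohort
}

# Map, exclude, window and score: everything upstream of the propensity
# model, shared by hdps_fit(), the k sweep and the one-by-one trajectory.
prepare_hdps <- function(cohort, events, maps,
                         outcome = "event",
                         cohort_def = c("include_triple", "exclude_triple"),
                         window_days = 365,
                         prespecified = prespecified_covariate_names(),
                         exclusions = NULL,
                         manual_map = NULL,
                         quantile_rule = "nearest_rank",
                         rr_cd_stratum = "unexposed",
                         log_rr_ce_cut = 1.1, log_rr_cd_cut = 0.5,
                         zero_correction = 0.1) {
  cohort_def <- match.arg(cohort_def)
  if (is.null(exclusions)) exclusions <- maps$exclusions
  n_input <- nrow(cohort)
  n_triple_excluded <- 0L
  if (cohort_def == "exclude_triple" && "triple_therapy" %in% names(cohort)) {
    drop <- cohort$exposure == 1L & cohort$triple_therapy == 1L
    n_triple_excluded <- sum(drop)
    cohort <- cohort[!drop, , drop = FALSE]
  }
  cohort <- apply_missing_data_rules(cohort)
  n_imd_dropped <- attr(cohort, "n_imd_dropped")
  events <- events[events$patient_id %in% cohort$patient_id, , drop = FALSE]

  obs <- map_and_truncate_observations(
    events[events$dimension == "observation", , drop = FALSE],
    table = maps$observation, manual = manual_map)
  hosp <- map_and_truncate_observations(
    events[events$dimension == "hospitalisation", , drop = FALSE],
    table = NULL)
  rx <- map_prescriptions(
    events[events$dimension == "prescription", , drop = FALSE],
    table = maps$prescription,
    fallback_table = maps$prescription_fallback,
    manual = manual_map)
  mapped <- combine_mapped_events(obs, hosp, rx)
  mapped <- apply_code_exclusions(mapped, exclusions)

  windowed <- restrict_assessment_window(mapped, window_days)
  rc <- build_recurrence_covariates(windowed, cohort$patient_id,
                                    ever_present_events = mapped,
                                    quantile_rule = quantile_rule)
  rc <- deduplicate_covariates(rc)

  X_prespec <- prespec_design_for(cohort, prespecified)
  scores <- score_covariates(rc, cohort$exposure, cohort[[outcome]],
                             rr_cd_stratum = rr_cd_stratum,
                             zero_correction = zero_correction)
  scores <- exclude_instrument_like(scores, log_rr_ce_cut, log_rr_cd_cut)
  scores <- rank_covariates(scores)

  list(cohort = cohort, rc = rc, scores = scores, X_prespec = X_prespec,
       unmapped = mapped$unmapped, outcome = outcome,
       cohort_def = cohort_def, prespecified = prespecified,
       ns = list(n_input = n_input, n_triple_excluded = n_triple_excluded,
                 n_imd_dropped = n_imd_dropped, n_analysis = nrow(cohort),
                 n_unmapped_events = sum(mapped$unmapped$n)))
}

# Dummy design over an arbitrary prespecified covariate subset.
prespec_design_for <- function(cohort, prespecified) {
  missing_cols <- setdiff(prespecified, names(cohort))
  if (length(missing_cols))
    stop("prespecified covariate(s) absent from the cohort: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ff <- stats::as.formula(paste("~", paste(prespecified, collapse = " + ")))
  mm <- stats::model.matrix(ff, data = cohort)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

# Propensity model + weights + trimming + outcome models for one design.
analyze_design <- function(X, prep, k_label, rd_se = "influence") {
  cohort <- prep$cohort
  ps_fit <- fit_propensity_model(X, cohort$exposure)
  trim <- trim_common_support(ps_fit$ps, cohort$exposure)
  keep <- trim$keep
  expo <- cohort$exposure[keep]
  w <- stabilized_weights(ps_fit$ps[keep], expo, p_exposed = mean(expo))
  tt <- cohort$time_to_event[keep]
  ev <- cohort[[prep$outcome]][keep]

  hr <- weighted_cox_hr(tt, ev, expo, w, k = k_label,
                        cohort = prep$cohort_def, outcome = prep$outcome)
  or <- weighted_logistic_or(ev, expo, w, k = k_label,
                             cohort = prep$cohort_def,
                             outcome = prep$outcome)
  rd <- weighted_risk_difference(ev, expo, w, se_method = rd_se,
                                 k = k_label, cohort = prep$cohort_def,
                                 outcome = prep$outcome)
  list(ps = ps_fit, trim = trim, weights = w,
       estimates = rbind(hr$estimate, or$estimate, rd$estimate),
       cox_fit = hr$fit,
       ph = schoenfeld_ph_check(hr$fit),
       km = weighted_survival_curves(tt, ev, expo, w),
       diagnostics = data.frame(
         k = k_label,
         max_weight = max(w),
         mean_weight = mean(w),
         ess_exposed = effective_sample_size(w[expo == 1L]),
         ess_unexposed = effective_sample_size(w[expo == 0L]),
         n_trimmed = sum(!keep)))
}

#' Fit a high-dimensional propensity score analysis
#'
#' End-to-end estimation of the exposure effect on a time-to-event
#' outcome in an active-comparator cohort: raw code events are harmonized
#' and pruned of exposure/outcome-defining codes, converted to binary
#' recurrence covariates within a 12-month assessment window, scored and
#' ranked with the Bross bias formula (instrument-like covariates
#' excluded), and the top `k` covariates are added to the prespecified set
#' in a logistic propensity model.  Stabilized ATE weights are formed,
#' trimmed to common support, and weighted Cox (hazard ratio), logistic
#' (odds ratio) and risk-difference models are fitted with robust
#' variances.  The conventional analysis (prespecified covariates only)
#' is always fitted alongside for comparison; `k = 0` reproduces it
#' exactly.
#'
#' Latent generator columns (`latent_severity`, `latent_frailty`) and any
#' other cohort columns outside `prespecified` never enter estimation.
#'
#' @param cohort patient table: `patient_id`, `exposure` (0/1),
#'   `time_to_event`, the outcome column, the prespecified covariates and
#'   optionally `triple_therapy`.
#' @param events long code-event table: `patient_id`, `dimension`,
#'   `raw_code`, `event_date` (days before index).
#' @param maps mapping tables as produced by [make_mapping_tables()] (or
#'   the same shape built from real files): `observation`, `prescription`,
#'   `prescription_fallback`, `exclusions`.
#' @param k number of top-ranked HDPS covariates to add (0 = conventional
#'   analysis only).
#' @param outcome name of the 0/1 outcome column (default `"event"`).
#' @param cohort_def `"include_triple"` keeps all patients;
#'   `"exclude_triple"` drops exposed triple-therapy users, the stricter
#'   active-comparator design.
#' @param window_days covariate-assessment window in days before index.
#' @param prespecified names of the investigator-specified covariate
#'   columns.
#' @param exclusions harmonized codes to exclude (defaults to
#'   `maps$exclusions`).
#' @param manual_map optional manual-override mapping table applied before
#'   the primary tables.
#' @param quantile_rule recurrence-threshold convention, see
#'   [build_recurrence_covariates()].
#' @param rr_cd_stratum,log_rr_ce_cut,log_rr_cd_cut,zero_correction
#'   prioritisation settings, see [crosstab_stats()] and
#'   [exclude_instrument_like()].
#' @param rd_se risk-difference SE method, see
#'   [weighted_risk_difference()].
#' @return An object of class `hdps_fit`; see [summary.hdps_fit()],
#'   [coef.hdps_fit()], [predict.hdps_fit()], [plot.hdps_fit()] and
#'   [effect_estimates()].
#' @export
hdps_fit <- function(cohort, events, maps, k = 250,
                     outcome = "event",
                     cohort_def = c("include_triple", "exclude_triple"),
                     window_days = 365,
                     prespecified = prespecified_covariate_names(),
                     exclusions = NULL,
                     manual_map = NULL,
                     quantile_rule = "nearest_rank",
                     rr_cd_stratum = "unexposed",
                     log_rr_ce_cut = 1.1, log_rr_cd_cut = 0.5,
                     zero_correction = 0.1,
                     rd_se = "influence") {
  cohort_def <- match.arg(cohort_def)
  stopifnot(k >= 0)
  prep <- prepare_hdps(cohort, events, maps, outcome = outcome,
                       cohort_def = cohort_def, window_days = window_days,
                       prespecified = prespecified,
                       exclusions = exclusions, manual_map = manual_map,
                       quantile_rule = quantile_rule,
                       rr_cd_stratum = rr_cd_stratum,
                       log_rr_ce_cut = log_rr_ce_cut,
                       log_rr_cd_cut = log_rr_cd_cut,
                       zero_correction = zero_correction)

  conventional <- analyze_design(prep$X_prespec, prep, k_label = 0L,
                                 rd_se = rd_se)
  selected <- character()
  hd <- NULL
  if (k > 0) {
    selected <- select_top_k(prep$scores, k)
    Xh <- cbind(prep$X_prespec,
                prep$rc$matrix[, selected, drop = FALSE])
    hd <- analyze_design(Xh, prep, k_label = as.integer(length(selected)),
                         rd_se = rd_se)
  }

  # balance of prespecified covariates (+ selected HDPS covariates) under
  # each weighting scheme, each on its own trimmed subset
  bal_cols <- c(
    stats::setNames(lapply(prep$prespecified,
                           function(cn) prep$cohort[[cn]]),
                    prep$prespecified),
    stats::setNames(lapply(selected,
                           function(id) prep$rc$matrix[, id]),
                    selected))
  smd_scheme <- function(an) {
    if (is.null(an)) return(NULL)
    keep <- an$trim$keep
    vapply(bal_cols, function(x)
      standardized_mean_difference(x[keep], prep$cohort$exposure[keep],
                                   an$weights), 0)
  }
  balance <- data.frame(covariate = names(bal_cols),
                        SMD_unweighted = vapply(bal_cols, function(x)
                          standardized_mean_difference(
                            x, prep$cohort$exposure), 0),
                        SMD_conventional = smd_scheme(conventional),
                        stringsAsFactors = FALSE)
  if (!is.null(hd)) balance$SMD_hdps <- smd_scheme(hd)
  rownames(balance) <- NULL

  primary <- if (!is.null(hd)) hd else conventional
  out <- list(call = match.call(), k = k, outcome = outcome,
              cohort_def = cohort_def,
              ns = prep$ns, unmapped = prep$unmapped,
              scores = prep$scores, covariate_meta = prep$rc$meta,
              selected = selected, prespecified = prep$prespecified,
              conventional = conventional, hdps = hd, primary = primary,
              balance = balance,
              exposure = prep$cohort$exposure,
              patient_ids = prep$cohort$patient_id)
  class(out) <- "hdps_fit"
  out
}

#' Tidy table of effect estimates from a fitted analysis
#'
#' @param fit an `hdps_fit` object.
#' @return Data frame with one row per (method, estimand): columns
#'   `method` (`"conventional"` or `"hdps_<k>"`), `estimand`, `point`,
#'   `se`, `lower`, `upper`, `k`, `cohort`, `outcome`.
#' @export
effect_estimates <- function(fit) {
  stopifnot(inherits(fit, "hdps_fit"))
  conv <- fit$conventional$estimates
  conv$method <- "conventional"
  out <- conv
  if (!is.null(fit$hdps)) {
    h <- fit$hdps$estimates
    h$method <- paste0("hdps_", fit$k)
    out <- rbind(conv, h)
  }
  out[, c("method", "estimand", "point", "se", "lower", "upper", "k",
          "cohort", "outcome")]
}

#' @export
print.hdps_fit <- function(x, ...) {
  cat(sprintf("HDPS analysis (%s, outcome '%s', k = %d)\n",
              x$cohort_def, x$outcome, x$k))
  cat(sprintf("  %d patients analysed (%d triple-therapy excluded, %d missing-IMD dropped)\n",
              x$ns$n_analysis, x$ns$n_triple_excluded, x$ns$n_imd_dropped))
  est <- effect_estimates(x)
  hr <- est[est$estimand == "HR", ]
  for (i in seq_len(nrow(hr)))
    cat(sprintf("  %-14s HR %.3f (95%% CI %.3f-%.3f)\n", hr$method[i],
                hr$point[i], hr$lower[i], hr$upper[i]))
  invisible(x)
}

#' Summarise a fitted HDPS analysis
#'
#' @param object an `hdps_fit` object.
#' @param ... unused.
#' @return Object of class `summary.hdps_fit`: effect estimates, balance
#'   summary, weight diagnostics, filter counts and the top of the
#'   covariate ranking.
#' @export
summary.hdps_fit <- function(object, ...) {
  diag <- object$conventional$diagnostics
  if (!is.null(object$hdps))
    diag <- rbind(diag, object$hdps$diagnostics)
  smd_cols <- grep("^SMD_", names(object$balance), value = TRUE)
  bal <- data.frame(
    scheme = sub("^SMD_", "", smd_cols),
    max_smd = vapply(smd_cols, function(cn)
      max(object$balance[[cn]], na.rm = TRUE), 0),
    n_above_0.1 = vapply(smd_cols, function(cn)
      sum(object$balance[[cn]] >= 0.1, na.rm = TRUE), 0L),
    row.names = NULL)
  top <- utils::head(object$scores[order(object$scores$rank,
                                         na.last = NA), ], 10L)
  out <- list(fit = object, estimates = effect_estimates(object),
              balance_summary = bal, diagnostics = diag, top_ranked = top,
              ph = object$primary$ph)
  class(out) <- "summary.hdps_fit"
  out
}

#' @export
print.summary.hdps_fit <- function(x, ...) {
  print(x$fit)
  cat("\nEffect estimates:\n")
  print(x$estimates, digits = 3, row.names = FALSE)
  cat("\nBalance (max SMD per weighting scheme):\n")
  print(x$balance_summary, digits = 3, row.names = FALSE)
  cat("\nWeight diagnostics:\n")
  print(x$diagnostics, digits = 3, row.names = FALSE)
  if (!is.null(x$ph$p_value) && !is.na(x$ph$p_value))
    cat(sprintf("\nProportional hazards check: chisq = %.2f, p = %.3f\n",
                x$ph$statistic, x$ph$p_value))
  cat(sprintf("\nTop-ranked covariates: %s ...\n",
              paste(utils::head(x$top_ranked$covariate_id, 5L),
                    collapse = ", ")))
  invisible(x)
}

#' Exposure-effect coefficients of a fitted analysis
#'
#' @param object an `hdps_fit` object.
#' @param ... unused.
#' @return Named vector from the primary analysis (HDPS when `k > 0`,
#'   else conventional): `log_HR`, `log_OR`, `RD`.
#' @export
coef.hdps_fit <- function(object, ...) {
  est <- object$primary$estimates
  c(log_HR = log(est$point[est$estimand == "HR"]),
    log_OR = log(est$point[est$estimand == "OR"]),
    RD = est$point[est$estimand == "RD"])
}

#' Propensity scores from a fitted analysis
#'
#' @param object an `hdps_fit` object.
#' @param newdata optional new cohort rows; only the conventional
#'   (prespecified-covariate) model can be applied to new data, since the
#'   HDPS design depends on the fitted cohort's code events.
#' @param model `"primary"`, `"conventional"` or `"hdps"`.
#' @param ... unused.
#' @return Numeric vector of propensity scores.
#' @export
predict.hdps_fit <- function(object, newdata = NULL,
                             model = c("primary", "conventional", "hdps"),
                             ...) {
  model <- match.arg(model)
  part <- switch(model, primary = object$primary,
                 conventional = object$conventional,
                 hdps = object$hdps)
  if (is.null(part)) stop("no HDPS model in this fit (k = 0)",
                          call. = FALSE)
  if (is.null(newdata)) return(part$ps$ps)
  if (model == "hdps" || (model == "primary" && !is.null(object$hdps)))
    stop("prediction on new data is only available for the conventional model",
         call. = FALSE)
  X <- prespec_design_for(newdata, object$prespecified)
  cf <- part$ps$coef
  Xf <- cbind(`(Intercept)` = 1, X)[, names(cf), drop = FALSE]
  as.numeric(stats::plogis(Xf %*% cf))
}

#' Plot overlap and balance diagnostics
#'
#' Two base-graphics panels: mirrored propensity-score densities by arm
#' (unweighted and weighted) and a dot chart of covariate SMDs per
#' weighting scheme with the 0.1 adequacy line.
#'
#' @param x an `hdps_fit` object.
#' @param which subset of `c("overlap", "balance")`.
#' @param ... unused.
#' @export
plot.hdps_fit <- function(x, which = c("overlap", "balance"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("overlap" %in% which) {
    ps <- x$primary$ps$ps
    dens <- ps_density(ps, x$exposure)
    d1 <- dens[dens$arm == "exposed", ]
    d0 <- dens[dens$arm == "unexposed", ]
    graphics::plot(d1$ps_grid, d1$density, type = "l", col = "firebrick",
                   xlab = "Propensity score", ylab = "Density",
                   main = "PS overlap",
                   ylim = range(0, d1$density, d0$density))
    graphics::lines(d0$ps_grid, d0$density, col = "steelblue")
    graphics::abline(v = c(x$primary$trim$lower, x$primary$trim$upper),
                     lty = 3)
    graphics::legend("topright", legend = c("exposed", "unexposed"),
                     col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  }
  if ("balance" %in% which) {
    bal <- x$balance[x$balance$covariate %in% x$prespecified, ]
    smd_cols <- grep("^SMD_", names(bal), value = TRUE)
    graphics::plot(NULL, xlim = range(0, unlist(bal[smd_cols]), 0.12),
                   ylim = c(1, nrow(bal)), yaxt = "n",
                   xlab = "Absolute SMD", ylab = "", main = "Balance")
    graphics::axis(2, at = seq_len(nrow(bal)), labels = bal$covariate,
                   las = 2, cex.axis = 0.6)
    pch <- c(1, 16, 17)
    for (i in seq_along(smd_cols))
      graphics::points(bal[[smd_cols[i]]], seq_len(nrow(bal)),
                       pch = pch[i])
    graphics::abline(v = 0.1, lty = 2)
    graphics::legend("topright", legend = sub("^SMD_", "", smd_cols),
                     pch = pch[seq_along(smd_cols)], bty = "n")
  }
  invisible(x)
}
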