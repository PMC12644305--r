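#' Run a complete simulated analysis
#'
#' Generates a synthetic dataset under `config` and fits the full
#' pipeline.  `k = 0` reproduces the conventional analysis.
#'
#' @param config a [sim_config()] object.
#' @param k number of HDPS covariates (0 = conventional).
#' @param cohort_def cohort definition, see [hdps_fit()].
#' @param outcome outcome column name.
#' @param ... further arguments passed to [hdps_fit()].
#' @return An `hdps_fit` object.
#' @export
run_analysis <- function(config, k = 250,
                         cohort_def = c("include_triple", "exclude_triple"),
                         outcome = "event", ...) {
  cohort_def <- match.arg(cohort_def)
  sim <- simulate_hdps_data(config)
  hdps_fit(sim$cohort, sim$events, sim$maps, k = k, outcome = outcome,
           cohort_def = cohort_def, ...)
}

#' Vary the number of HDPS covariates
#'
#' Refits the propensity and outcome models over a grid of covariate
#' counts (the preparation stage - mapping, covariate construction,
#' prioritisation - is computed once and frozen).  `k = 0` rows are the
#' conventional analysis.
#'
#' @param cohort,events,maps analysis inputs, see [hdps_fit()].
#' @param k_values integer grid; the published grid is
#'   `c(0, 100, 250, 500, 750, 1000)`.
#' @param ... preparation options passed to the pipeline (outcome,
#'   cohort_def, window_days, cutoffs, ...).
#' @param rd_se risk-difference SE method.
#' @return Data frame of effect estimates with diagnostics, one block per
#'   `k`.
#' @export
hdps_k_sweep <- function(cohort, events, maps,
                         k_values = c(0, 100, 250, 500, 750, 1000),
                         rd_se = "influence", ...) {
  prep <- prepare_hdps(cohort, events, maps, ...)
  out <- list()
  for (k in k_values) {
    X <- prep$X_prespec
    if (k > 0) {
      sel <- select_top_k(prep$scores, k)
      X <- cbind(prep$X_prespec, prep$rc$matrix[, sel, drop = FALSE])
    }
    an <- analyze_design(X, prep, k_label = as.integer(k), rd_se = rd_se)
    est <- an$estimates
    est$max_weight <- an$diagnostics$max_weight
    est$ess_exposed <- an$diagnostics$ess_exposed
    est$ess_unexposed <- an$diagnostics$ess_unexposed
    out[[as.character(k)]] <- est
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-by-one covariate sensitivity trajectory
#'
#' Adds the Bross-ranked covariates to the propensity model one at a
#' time, refitting the propensity and weighted Cox models from scratch at
#' each step, and records the effect estimate together with the maximum
#' stabilized weight and the per-arm effective sample sizes.  Large
#' single-step jumps reveal covariates whose rare combinations give a few
#' outcome patients extreme weights - the instability mode this analysis
#' exists to detect.  The ranking is computed once and frozen before the
#' loop.
#'
#' @param cohort,events,maps analysis inputs, see [hdps_fit()].
#' @param max_rank deepest rank to include (default 250); truncated with
#'   a warning when fewer covariates are available.
#' @param rd_se unused here (Cox only); present for signature symmetry.
#' @param ... preparation options passed to the pipeline.
#' @return Object of class `hdps_trajectory`: a data frame with one row
#'   per step (`n_covariates`, `covariate_id` of the covariate added,
#'   `point`, `lower`, `upper` on the HR scale, `max_weight`,
#'   `ess_exposed`, `ess_unexposed`).
#' @export
one_by_one_trajectory <- function(cohort, events, maps, max_rank = 250,
                                  rd_se = "influence", ...) {
  prep <- prepare_hdps(cohort, events, maps, ...)
  n_ret <- sum(!is.na(prep$scores$rank))
  if (max_rank > n_ret) {
    warning(sprintf("max_rank = %d exceeds the %d retained covariates; truncating",
                    max_rank, n_ret))
    max_rank <- n_ret
  }
  ids <- prep$scores$covariate_id[order(prep$scores$rank,
                                        na.last = NA)][seq_len(max_rank)]
  cohort2 <- prep$cohort
  rows <- vector("list", max_rank)
  for (j in seq_len(max_rank)) {
    X <- cbind(prep$X_prespec,
               prep$rc$matrix[, ids[seq_len(j)], drop = FALSE])
    ps_fit <- fit_propensity_model(X, cohort2$exposure)
    trim <- trim_common_support(ps_fit$ps, cohort2$exposure)
    keep <- trim$keep
    expo <- cohort2$exposure[keep]
    w <- stabilized_weights(ps_fit$ps[keep], expo, p_exposed = mean(expo))
    hr <- weighted_cox_hr(cohort2$time_to_event[keep],
                          cohort2[[prep$outcome]][keep], expo, w,
                          k = j, cohort = prep$cohort_def,
                          outcome = prep$outcome)
    est <- hr$estimate
    rows[[j]] <- data.frame(
      n_covariates = j, covariate_id = ids[j],
      point = est$point, lower = est$lower, upper = est$upper,
      max_weight = max(w),
      ess_exposed = effective_sample_size(w[expo == 1L]),
      ess_unexposed = effective_sample_size(w[expo == 0L]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hdps_trajectory", "data.frame")
  out
}

#' @export
plot.hdps_trajectory <- function(x, ...) {
  graphics::plot(x$n_covariates, x$point, type = "l", log = "y",
                 xlab = "Number of HDPS covariates",
                 ylab = "Hazard ratio",
                 main = "One-by-one covariate sensitivity",
                 ylim = range(x$lower, x$upper))
  graphics::lines(x$n_covariates, x$lower, lty = 3)
  graphics::lines(x$n_covariates, x$upper, lty = 3)
  graphics::abline(h = 1, col = "grey60")
  invisible(x)
}
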