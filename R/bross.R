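#' @title Bross-formula covariate prioritisation
#' @description Candidate covariates are ranked by their potential to bias
#'   the exposure-outcome association, using the bias multiplier of an
#'   unmeasured binary confounder: a function of the covariate's prevalence
#'   in each exposure arm and its relative risk with the outcome.
#'   Covariates that behave like instrumental variables (strong exposure
#'   association, negligible outcome association) are flagged and removed
#'   from the ranking, since adjusting for them can amplify bias.
#' @name prioritisation
NULL

corrected_rr <- function(x1, n1, x0, n0, zero_correction) {
  if (min(x1, n1 - x1, x0, n0 - x0) == 0) {
    x1 <- x1 + zero_correction; n1 <- n1 + 2 * zero_correction
    x0 <- x0 + zero_correction; n0 <- n0 + 2 * zero_correction
  }
  (x1 / n1) / (x0 / n0)
}

#' Prevalence and relative-risk statistics for one candidate covariate
#'
#' Computes the covariate's prevalence among the exposed (`P_C1`) and
#' unexposed (`P_C0`), the covariate-exposure relative risk
#' `RR_CE = P_C1 / P_C0`, and the covariate-outcome relative risk `RR_CD`
#' (risk of the outcome in covariate-positive vs covariate-negative
#' patients), estimated by default within the unexposed stratum so that
#' the exposure effect itself cannot contaminate it.  Whenever a 2x2 table
#' contains a zero cell, `zero_correction` is added to every cell of that
#' table before the ratio is formed.
#'
#' @param covariate,exposure,outcome binary 0/1 vectors of equal length.
#' @param rr_cd_stratum `"unexposed"` (default) or `"all"`: the stratum in
#'   which `RR_CD` is estimated.
#' @param zero_correction value added to each cell of a 2x2 with any zero
#'   cell (default 0.1).
#' @return Named list: `P_C1`, `P_C0`, `RR_CE`, `RR_CD`.
#' @export
crosstab_stats <- function(covariate, exposure, outcome,
                           rr_cd_stratum = c("unexposed", "all"),
                           zero_correction = 0.1) {
  rr_cd_stratum <- match.arg(rr_cd_stratum)
  stopifnot(length(covariate) == length(exposure),
            length(covariate) == length(outcome))
  if (!all(covariate %in% 0:1) || !all(exposure %in% 0:1) ||
      !all(outcome %in% 0:1))
    stop("covariate, exposure and outcome must be binary 0/1",
         call. = FALSE)
  n1 <- sum(exposure == 1L); n0 <- sum(exposure == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("an exposure arm has zero patients", call. = FALSE)

  c1 <- sum(covariate[exposure == 1L])
  c0 <- sum(covariate[exposure == 0L])
  P_C1 <- c1 / n1
  P_C0 <- c0 / n0
  RR_CE <- corrected_rr(c1, n1, c0, n0, zero_correction)

  keep <- if (rr_cd_stratum == "unexposed") exposure == 0L else
    rep(TRUE, length(exposure))
  cc <- covariate[keep]; dd <- outcome[keep]
  d1 <- sum(dd[cc == 1L]); m1 <- sum(cc == 1L)
  d0 <- sum(dd[cc == 0L]); m0 <- sum(cc == 0L)
  RR_CD <- corrected_rr(d1, m1, d0, m0, zero_correction)

  list(P_C1 = P_C1, P_C0 = P_C0, RR_CE = RR_CE, RR_CD = RR_CD)
}

#' Bross bias multiplier for an unmeasured binary confounder
#'
#' `bias = (P_C1 (RR - 1) + 1) / (P_C0 (RR - 1) + 1)`, where `RR` is the
#' covariate-outcome relative risk; when `RR_CD < 1` its reciprocal is
#' used, so protective and harmful covariate-outcome associations rank
#' symmetrically.  The ranking statistic is `|log(bias)|`.
#'
#' @param P_C1,P_C0 covariate prevalence among exposed / unexposed.
#' @param RR_CD covariate-outcome relative risk (> 0).
#' @return Named list: `bias_mult`, `abs_log_bias`.
#' @export
bross_bias <- function(P_C1, P_C0, RR_CD) {
  if (any(!is.finite(c(P_C1, P_C0, RR_CD))))
    stop("inputs to the bias formula must be finite", call. = FALSE)
  if (any(RR_CD <= 0))
    stop("RR_CD must be positive after zero-cell correction",
         call. = FALSE)
  rr <- ifelse(RR_CD < 1, 1 / RR_CD, RR_CD)
  bias <- (P_C1 * (rr - 1) + 1) / (P_C0 * (rr - 1) + 1)
  list(bias_mult = bias, abs_log_bias = abs(log(bias)))
}

#' Score all candidate covariates against exposure and outcome
#'
#' Vectorised application of [crosstab_stats()] and [bross_bias()] over
#' the columns of a 0/1 covariate matrix.  Prioritisation is
#' outcome-specific: scores must be recomputed for each outcome studied.
#'
#' @param covariates a `recurrence_covariates` object or 0/1 matrix with
#'   column names used as covariate ids.
#' @param exposure,outcome binary 0/1 vectors over the matrix rows.
#' @inheritParams crosstab_stats
#' @return Data frame of class `bross_scores` with one row per covariate:
#'   `covariate_id`, `P_C1`, `P_C0`, `RR_CE`, `RR_CD`, `bias_mult`,
#'   `abs_log_bias`, `iv_flag` (all `FALSE` until
#'   [exclude_instrument_like()]), `rank` (`NA` until
#'   [rank_covariates()]).
#' @export
score_covariates <- function(covariates, exposure, outcome,
                             rr_cd_stratum = c("unexposed", "all"),
                             zero_correction = 0.1) {
  rr_cd_stratum <- match.arg(rr_cd_stratum)
  mat <- if (inherits(covariates, "recurrence_covariates"))
    covariates$matrix else covariates
  stopifnot(nrow(mat) == length(exposure),
            nrow(mat) == length(outcome))
  n1 <- sum(exposure == 1L); n0 <- sum(exposure == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("an exposure arm has zero patients", call. = FALSE)

  e <- as.numeric(exposure); d <- as.numeric(outcome)
  c1 <- drop(crossprod(mat, e))
  ctot <- colSums(mat)
  c0 <- ctot - c1
  P_C1 <- c1 / n1
  P_C0 <- c0 / n0

  corr_vec <- function(x1, m1, x0, m0) {
    z <- pmin(x1, m1 - x1, x0, m0 - x0) == 0
    x1c <- ifelse(z, x1 + zero_correction, x1)
    m1c <- ifelse(z, m1 + 2 * zero_correction, m1)
    x0c <- ifelse(z, x0 + zero_correction, x0)
    m0c <- ifelse(z, m0 + 2 * zero_correction, m0)
    (x1c / m1c) / (x0c / m0c)
  }
  RR_CE <- corr_vec(c1, rep(n1, length(c1)), c0, rep(n0, length(c0)))

  keep <- if (rr_cd_stratum == "unexposed") exposure == 0L else
    rep(TRUE, length(exposure))
  sub <- mat[keep, , drop = FALSE]
  ds <- d[keep]
  m1 <- colSums(sub)
  m0 <- nrow(sub) - m1
  d1 <- drop(crossprod(sub, ds))
  d0 <- sum(ds) - d1
  RR_CD <- corr_vec(d1, m1, d0, m0)

  bb <- bross_bias(P_C1, P_C0, RR_CD)
  out <- data.frame(
    covariate_id = colnames(mat),
    P_C1 = P_C1, P_C0 = P_C0, RR_CE = RR_CE, RR_CD = RR_CD,
    bias_mult = bb$bias_mult, abs_log_bias = bb$abs_log_bias,
    iv_flag = FALSE, rank = NA_integer_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bross_scores", "data.frame")
  out
}

#' Flag instrument-like covariates
#'
#' A covariate is flagged when `|log RR_CE| > log_rr_ce_cut` and
#' `|log RR_CD| < log_rr_cd_cut` (defaults 1.1 and 0.5): strongly
#' associated with exposure, essentially unassociated with the outcome.
#' Flagged covariates are removed from the ranking by
#' [rank_covariates()].
#'
#' @param scores a `bross_scores` data frame.
#' @param log_rr_ce_cut,log_rr_cd_cut cutoffs on the absolute log relative
#'   risks.
#' @return The scores with `iv_flag` set.
#' @export
exclude_instrument_like <- function(scores, log_rr_ce_cut = 1.1,
                                    log_rr_cd_cut = 0.5) {
  stopifnot(inherits(scores, "bross_scores") || is.data.frame(scores))
  scores$iv_flag <- abs(log(scores$RR_CE)) > log_rr_ce_cut &
    abs(log(scores$RR_CD)) < log_rr_cd_cut
  scores
}

#' Rank covariates by confounding potential
#'
#' Orders non-flagged covariates by descending `abs_log_bias`, breaking
#' exact ties lexicographically on `covariate_id` for reproducibility.
#' Flagged covariates keep `rank = NA`.
#'
#' @param scores a `bross_scores` data frame (after
#'   [exclude_instrument_like()] if instrument exclusion is wanted).
#' @return The scores with `rank` filled in (a permutation of
#'   `1..n_retained`).
#' @export
rank_covariates <- function(scores) {
  retained <- which(!scores$iv_flag)
  ord <- retained[order(-scores$abs_log_bias[retained],
                        scores$covariate_id[retained])]
  scores$rank <- NA_integer_
  scores$rank[ord] <- seq_along(ord)
  scores
}

#' Select the top-k ranked covariates
#'
#' @param scores ranked `bross_scores`.
#' @param k number of covariates to select; if `k` exceeds the number of
#'   retained covariates, all are used with a warning.
#' @return Character vector of covariate ids with ranks `1..k`.
#' @export
select_top_k <- function(scores, k) {
  if (all(is.na(scores$rank)))
    stop("scores are unranked; call rank_covariates() first", call. = FALSE)
  n_ret <- sum(!is.na(scores$rank))
  if (k > n_ret) {
    warning(sprintf("k = %d exceeds the %d retained covariates; using all",
                    k, n_ret))
    k <- n_ret
  }
  ids <- scores$covariate_id[order(scores$rank, na.last = NA)]
  ids[seq_len(k)]
}

#' Dimension provenance of the top-ranked covariates
#'
#' Counts how many of the top-k covariates come from each care dimension
#' (covariate ids are `"{dim}:{code}:{level}"`).
#'
#' @param scores ranked `bross_scores`.
#' @param k number of top covariates to summarise.
#' @return Data frame: `dimension`, `n`, `pct`.
#' @export
dimension_summary <- function(scores, k) {
  ids <- select_top_k(scores, k)
  dims <- vapply(strsplit(ids, ":", fixed = TRUE), `[[`, "", 1L)
  tab <- table(dims)
  out <- data.frame(dimension = names(tab), n = as.integer(tab),
                    pct = 100 * as.integer(tab) / length(ids),
                    stringsAsFactors = FALSE)
  out[order(-out$n), , drop = FALSE]
}
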