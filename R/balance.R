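#' Standardized mean difference between treatment groups
#'
#' For binary or continuous columns:
#' `|m1 - m0| / sqrt((v1 + v0) / 2)` with (optionally weighted) group
#' means and variances.  Weighted variances use the frequency-weight form
#' `sum(w (x - m)^2) / (sum(w) - 1)` about the weighted mean.  For factor
#' columns a multi-category Mahalanobis-type statistic is used over the
#' K-1 level-proportion vectors, so one SMD is reported per categorical
#' covariate.  If the pooled variance is zero while the means differ, the
#' SMD is `Inf` (a flagged value); identical degenerate distributions give
#' 0.
#'
#' @param x numeric vector or factor.
#' @param exposure binary 0/1 vector.
#' @param weights optional positive weights (default: all 1).
#' @return A non-negative number.
#' @export
standardized_mean_difference <- function(x, exposure, weights = NULL) {
  stopifnot(length(x) == length(exposure))
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), all(weights > 0))
  e1 <- exposure == 1L; e0 <- exposure == 0L

  if (is.factor(x) || is.character(x)) {
    x <- as.factor(x)
    lv <- levels(x)
    if (length(lv) < 2L) return(0)
    prop <- function(sel) {
      w <- weights[sel]
      vapply(lv, function(l) sum(w[x[sel] == l]) / sum(w), 0)
    }
    p1 <- prop(e1)[-1L]; p0 <- prop(e0)[-1L]
    d <- p1 - p0
    if (all(d == 0)) return(0)
    K <- length(d)
    S <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K)) {
      S[i, j] <- if (i == j)
        (p1[i] * (1 - p1[i]) + p0[i] * (1 - p0[i])) / 2
      else
        -(p1[i] * p1[j] + p0[i] * p0[j]) / 2
    }
    val <- tryCatch(drop(t(d) %*% solve(S, d)),
                    error = function(e) drop(t(d) %*% MASS::ginv(S) %*% d))
    return(sqrt(max(val, 0)))
  }

  wmean <- function(sel) sum(weights[sel] * x[sel]) / sum(weights[sel])
  wvar <- function(sel, m) {
    sw <- sum(weights[sel])
    sum(weights[sel] * (x[sel] - m)^2) / (sw - 1)
  }
  m1 <- wmean(e1); m0 <- wmean(e0)
  v1 <- wvar(e1, m1); v0 <- wvar(e0, m0)
  pooled <- (v1 + v0) / 2
  if (pooled == 0) return(if (m1 == m0) 0 else Inf)
  abs(m1 - m0) / sqrt(pooled)
}

#' Covariate balance table across weighting schemes
#'
#' Computes the standardized mean difference of every supplied covariate
#' under each weighting scheme (typically unweighted, conventional-PS
#' weighted, and HDPS weighted), mirroring the SMD columns of a baseline
#' characteristics table.
#'
#' @param covariates data frame (factors allowed) or numeric matrix.
#' @param exposure binary 0/1 vector.
#' @param weights named list of weight vectors; `NULL` entries mean
#'   unweighted.
#' @return Data frame: `covariate` plus one `SMD_<name>` column per
#'   weighting scheme.
#' @export
balance_table <- function(covariates, exposure,
                          weights = list(unweighted = NULL)) {
  cols <- if (is.matrix(covariates))
    stats::setNames(lapply(seq_len(ncol(covariates)),
                           function(j) covariates[, j]),
                    colnames(covariates))
  else as.list(covariates)
  out <- data.frame(covariate = names(cols), stringsAsFactors = FALSE)
  for (wn in names(weights)) {
    out[[paste0("SMD_", wn)]] <- vapply(cols, function(x)
      standardized_mean_difference(x, exposure, weights[[wn]]), 0)
  }
  rownames(out) <- NULL
  out
}

#' Propensity-score density data for overlap plots
#'
#' Kernel density of the PS per treatment arm, optionally weighted, on a
#' common grid; suitable for mirrored-density overlap displays or export.
#'
#' @param ps propensity scores.
#' @param exposure binary 0/1 vector.
#' @param weights optional weights.
#' @param n grid size.
#' @return Data frame: `ps_grid`, `density`, `arm`.
#' @export
ps_density <- function(ps, exposure, weights = NULL, n = 256) {
  if (is.null(weights)) weights <- rep(1, length(ps))
  grid <- seq(min(ps), max(ps), length.out = n)
  one_arm <- function(sel, label) {
    w <- weights[sel] / sum(weights[sel])
    d <- stats::density(ps[sel], weights = w, from = min(grid),
                        to = max(grid), n = n)
    data.frame(ps_grid = d$x, density = d$y, arm = label,
               stringsAsFactors = FALSE)
  }
  rbind(one_arm(exposure == 1L, "exposed"),
        one_arm(exposure == 0L, "unexposed"))
}
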