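#' Fit a propensity-score model
#'
#' Logistic regression of exposure on the supplied covariate columns
#' (prespecified covariates, optionally augmented with selected
#' high-dimensional covariates).  Rank-deficient design matrices have
#' their aliased columns dropped with a warning; (quasi-)complete
#' separation is detected and reported as an error naming the offending
#' columns, since a separated propensity model cannot produce usable
#' weights.
#'
#' @param x numeric design matrix (no intercept column; one is added), or
#'   a data frame of covariates which is expanded with
#'   [stats::model.matrix()].
#' @param exposure binary 0/1 vector.
#' @return Object of class `propensity_result`: list with `ps` (fitted
#'   probability of exposure), `coef` (including intercept), `p_exposed`
#'   (marginal exposure prevalence), `dropped` (aliased columns removed)
#'   and `converged`.
#' @export
fit_propensity_model <- function(x, exposure) {
  if (is.data.frame(x))
    x <- stats::model.matrix(~ ., data = x)[, -1L, drop = FALSE]
  stopifnot(is.matrix(x) || ncol(x) == 0L)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing values in the covariate matrix", call. = FALSE)
  stopifnot(nrow(x) == length(exposure))
  y <- as.numeric(exposure)

  X <- cbind(`(Intercept)` = 1, x)
  dropped <- character()
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    warning(sprintf("dropping %d collinear column(s): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())
  )
  eps <- 1e-8
  boundary <- fit$fitted.values < eps | fit$fitted.values > 1 - eps
  big <- abs(fit$coefficients) > 15
  big[is.na(big)] <- FALSE
  if (any(boundary) && any(big[-1L])) {
    stop("perfect separation in the propensity model; offending column(s): ",
         paste(colnames(X)[-1L][big[-1L]], collapse = ", "), call. = FALSE)
  }
  if (!fit$converged)
    stop("propensity model did not converge", call. = FALSE)
  structure(list(ps = as.numeric(fit$fitted.values),
                 coef = fit$coefficients,
                 p_exposed = mean(y),
                 dropped = dropped,
                 converged = fit$converged),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("Propensity model: %d patients, %d coefficients, exposure prevalence %.3f\n",
              length(x$ps), length(x$coef), x$p_exposed))
  cat(sprintf("  PS range: [%.4f, %.4f]\n", min(x$ps), max(x$ps)))
  if (length(x$dropped))
    cat("  dropped collinear columns:", length(x$dropped), "\n")
  invisible(x)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' ATE weights with the marginal exposure prevalence in the numerator:
#' exposed patients receive `p_E / PS`, unexposed `(1 - p_E) / (1 - PS)`.
#' Stabilization bounds the weight variance and makes the mean weight
#' approximately 1.
#'
#' @param ps propensity scores, strictly inside (0, 1).
#' @param exposure binary 0/1 vector.
#' @param p_exposed marginal exposure prevalence (defaults to
#'   `mean(exposure)`).
#' @return Numeric vector of positive weights.
#' @export
stabilized_weights <- function(ps, exposure, p_exposed = mean(exposure)) {
  stopifnot(length(ps) == length(exposure))
  if (any(ps <= 0 | ps >= 1))
    stop("propensity scores of exactly 0 or 1 cannot be weighted",
         call. = FALSE)
  ifelse(exposure == 1L, p_exposed / ps, (1 - p_exposed) / (1 - ps))
}

#' Trim to the region of common propensity-score support
#'
#' The retained region is `[max(groupwise minima), min(groupwise maxima)]`
#' (bounds inclusive): the PS range where both treatment groups are
#' represented.  Re-applying the operation to the retained set leaves the
#' bounds nested inside the originals; with continuous scores it can shave
#' a handful of new boundary patients (the bounds themselves were removed
#' from the opposite group), so exclusion counts are reported and the
#' pipeline applies the trim exactly once per analysis.
#'
#' @param ps propensity scores.
#' @param exposure binary 0/1 vector; both groups must be non-empty.
#' @return List: `lower`, `upper`, `keep` (logical mask), `n_excluded`
#'   (named, per arm).
#' @export
trim_common_support <- function(ps, exposure) {
  stopifnot(length(ps) == length(exposure))
  e1 <- exposure == 1L; e0 <- exposure == 0L
  if (!any(e1) || !any(e0))
    stop("both treatment groups must be non-empty", call. = FALSE)
  lower <- max(min(ps[e1]), min(ps[e0]))
  upper <- min(max(ps[e1]), max(ps[e0]))
  if (lower > upper)
    stop("no common support: the groupwise PS ranges are disjoint",
         call. = FALSE)
  keep <- ps >= lower & ps <= upper
  list(lower = lower, upper = upper, keep = keep,
       n_excluded = c(exposed = sum(!keep & e1),
                      unexposed = sum(!keep & e0)))
}

#' Effective sample size of a weighted group
#'
#' `(sum w)^2 / sum(w^2)`; shrinks towards 1 when a few observations carry
#' extreme weights, which is the pathology that drives instability in
#' one-by-one covariate sensitivity analyses.
#'
#' @param w positive weights.
#' @return A single number.
#' @export
effective_sample_size <- function(w) {
  sum(w)^2 / sum(w^2)
}
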