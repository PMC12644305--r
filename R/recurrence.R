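#' Restrict mapped events to the covariate-assessment window
#'
#' Keeps events recorded between 1 and `window_days` days before the index
#' date (inclusive); events on the index date itself are excluded by the
#' `event_date >= 1` convention.
#'
#' @param mapped a `mapped_events` object or mapped events data frame with
#'   an `event_date` column in days before index.
#' @param window_days length of the assessment window (default 365).
#' @return Same type as `mapped`, restricted to the window.
#' @export
restrict_assessment_window <- function(mapped, window_days = 365) {
  if (length(window_days) != 1L || !is.finite(window_days) ||
      window_days <= 0)
    stop("'window_days' must be a positive number", call. = FALSE)
  if (inherits(mapped, "mapped_events")) {
    mapped$events <- restrict_assessment_window(mapped$events, window_days)
    return(mapped)
  }
  out <- mapped[mapped$event_date >= 1 & mapped$event_date <= window_days, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

# Quantile of positive integer counts under the declared convention.
count_quantile <- function(pos, q, rule) {
  m <- length(pos)
  switch(rule,
         nearest_rank = sort(pos)[ceiling(q * m)],
         type7 = unname(stats::quantile(pos, q, type = 7)),
         stop("unknown quantile rule: ", rule, call. = FALSE))
}

#' Build binary recurrence covariates from mapped code events
#'
#' For each (dimension, harmonized code) with at least one occurrence in
#' the assessment window, three nested binary patient-level covariates are
#' created from the per-patient occurrence count: `once` (count >= 1),
#' `sporadic` (count >= median of the positive counts) and `frequent`
#' (count >= 75th percentile of the positive counts).  Thresholds are
#' computed among patients with >= 1 occurrence, and ties at the threshold
#' qualify (`>=`).  For the observation dimension the `once` covariate is
#' redefined as "code ever recorded before the index date", using the
#' unrestricted event stream, to capture chronic conditions that are not
#' re-recorded at every consultation; `sporadic` and `frequent` still use
#' windowed counts.  No marginal-prevalence filter is applied.
#'
#' @param windowed mapped events restricted to the assessment window
#'   (`mapped_events` object or data frame).
#' @param patient_ids vector of patient ids defining the rows of the
#'   covariate matrix (patients without events get all-zero rows).
#' @param ever_present_events optional unrestricted event stream for the
#'   observation dimension (a `mapped_events` object or data frame); when
#'   supplied, observation `once` covariates use it.
#' @param quantile_rule `"nearest_rank"` (k-th smallest positive count
#'   with k = ceiling(q m); integer thresholds, no interpolation) or
#'   `"type7"` (R's default interpolating quantile).
#' @return An object of class `recurrence_covariates`: a list with
#'   `matrix` (patients x covariates, 0/1 integer, columns named
#'   `"{dim}:{code}:{level}"`), `meta` (id, dimension, code, level,
#'   threshold) and `patient_ids`.
#' @export
build_recurrence_covariates <- function(windowed, patient_ids,
                                        ever_present_events = NULL,
                                        quantile_rule = c("nearest_rank",
                                                          "type7")) {
  quantile_rule <- match.arg(quantile_rule)
  if (inherits(windowed, "mapped_events")) windowed <- windowed$events
  if (inherits(ever_present_events, "mapped_events"))
    ever_present_events <- ever_present_events$events
  n <- length(patient_ids)

  key <- paste(windowed$dimension, windowed$harmonized_code, sep = ":")
  keys <- sort(unique(key))
  ki <- match(key, keys)
  pi_ <- match(windowed$patient_id, patient_ids)
  if (anyNA(pi_))
    stop("events reference patients absent from 'patient_ids'",
         call. = FALSE)
  counts <- matrix(tabulate((ki - 1L) * n + pi_, nbins = length(keys) * n),
                   nrow = n, ncol = length(keys))

  # ever-present indicator per observation code, if the stream is supplied
  ever <- NULL
  if (!is.null(ever_present_events)) {
    obs <- ever_present_events[
      ever_present_events$dimension == "observation", , drop = FALSE]
    ek <- paste(obs$dimension, obs$harmonized_code, sep = ":")
    ever <- lapply(split(match(obs$patient_id, patient_ids), ek), unique)
  }

  cols <- list(); meta <- list()
  levels_ <- c("once", "sporadic", "frequent")
  for (j in seq_along(keys)) {
    cnt <- counts[, j]
    pos <- cnt[cnt > 0L]
    if (!length(pos)) next
    parts <- strsplit(keys[j], ":", fixed = TRUE)[[1L]]
    dimension <- parts[1L]; code <- parts[2L]
    thr <- c(once = 1,
             sporadic = count_quantile(pos, 0.5, quantile_rule),
             frequent = count_quantile(pos, 0.75, quantile_rule))
    for (lv in levels_) {
      col <- as.integer(cnt >= thr[[lv]])
      if (lv == "once" && dimension == "observation" && !is.null(ever)) {
        idx <- ever[[keys[j]]]
        col <- integer(n)
        col[idx[!is.na(idx)]] <- 1L
        # windowed occurrences are necessarily ever-present
        col[cnt > 0L] <- 1L
      }
      id <- paste(dimension, code, lv, sep = ":")
      cols[[id]] <- col
      meta[[id]] <- data.frame(id = id, dimension = dimension, code = code,
                               level = lv, threshold = unname(thr[[lv]]),
                               stringsAsFactors = FALSE)
    }
  }
  mat <- if (length(cols)) do.call(cbind, cols) else
    matrix(integer(), nrow = n, ncol = 0L)
  meta_df <- if (length(meta)) do.call(rbind, meta) else
    data.frame(id = character(), dimension = character(),
               code = character(), level = character(),
               threshold = numeric(), stringsAsFactors = FALSE)
  rownames(meta_df) <- NULL
  structure(list(matrix = mat, meta = meta_df, patient_ids = patient_ids,
                 quantile_rule = quantile_rule),
            class = "recurrence_covariates")
}

#' @export
print.recurrence_covariates <- function(x, ...) {
  cat(sprintf("Recurrence covariates: %d patients x %d covariates (%d codes; quantile rule: %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$meta$code)), x$quantile_rule))
  invisible(x)
}

#' Collapse degenerate recurrence levels within a code
#'
#' When two recurrence levels of the same (dimension, code) produce
#' identical columns over all patients (e.g., every positive count equals
#' 1, so once = sporadic = frequent), only the lowest level is kept.  This
#' prevents perfectly collinear duplicates from entering the propensity
#' model.  Deduplication is within-code only: distinct codes with
#' coincidentally equal columns are both retained.
#'
#' @param rc a `recurrence_covariates` object.
#' @return The object with duplicate columns removed.
#' @export
deduplicate_covariates <- function(rc) {
  stopifnot(inherits(rc, "recurrence_covariates"))
  if (!ncol(rc$matrix)) return(rc)
  keep <- rep(TRUE, ncol(rc$matrix))
  meta <- rc$meta
  grp <- paste(meta$dimension, meta$code, sep = ":")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    # order once < sporadic < frequent
    lv_order <- match(meta$level[idx], c("once", "sporadic", "frequent"))
    idx <- idx[order(lv_order)]
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || !keep[idx[b]]) next
        if (identical(rc$matrix[, idx[a]], rc$matrix[, idx[b]]))
          keep[idx[b]] <- FALSE
      }
    }
  }
  rc$matrix <- rc$matrix[, keep, drop = FALSE]
  rc$meta <- meta[keep, , drop = FALSE]
  rownames(rc$meta) <- NULL
  rc
}
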