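#' @title Code mapping and harmonization
#' @description Harmonize raw dimension codes to the analysis vocabulary:
#'   3-character ICD-like classes for observations and hospitalisations,
#'   6-character formulary-paragraph classes for prescriptions.  Events
#'   whose raw code cannot be resolved are dropped from the mapped table
#'   and tallied in an unmapped-code report (mirroring the "top unmapped
#'   codes" tables such analyses publish).  Matching is case-sensitive.
#' @name code_mapping
NULL

new_mapped_events <- function(events, unmapped_codes) {
  if (length(unmapped_codes)) {
    tab <- table(unmapped_codes)
    rep_df <- data.frame(code = names(tab), n = as.integer(tab),
                         stringsAsFactors = FALSE)
    rep_df <- rep_df[order(-rep_df$n, rep_df$code), , drop = FALSE]
  } else {
    rep_df <- data.frame(code = character(), n = integer(),
                         stringsAsFactors = FALSE)
  }
  rownames(rep_df) <- NULL
  rownames(events) <- NULL
  structure(list(events = events, unmapped = rep_df),
            class = "mapped_events")
}

#' @export
print.mapped_events <- function(x, ...) {
  cat(sprintf("Mapped code events: %d events, %d harmonized codes, %d unmapped raw codes (%d events dropped)\n",
              nrow(x$events), length(unique(x$events$harmonized_code)),
              nrow(x$unmapped), sum(x$unmapped$n)))
  invisible(x)
}

check_mapping_table <- function(table, what = "mapping table") {
  if (is.null(table)) return(invisible(NULL))
  stopifnot(is.data.frame(table),
            all(c("source_code", "target_code") %in% names(table)))
  if (anyDuplicated(table$source_code))
    stop(sprintf("duplicate source codes in %s", what), call. = FALSE)
  if (any(!nzchar(table$target_code)))
    stop(sprintf("empty target codes in %s", what), call. = FALSE)
  invisible(NULL)
}

lookup <- function(codes, table) {
  if (is.null(table) || nrow(table) == 0L) return(rep(NA_character_,
                                                      length(codes)))
  table$target_code[match(codes, table$source_code)]
}

#' Map observation or hospitalisation codes and truncate to 3 characters
#'
#' Raw clinical codes are resolved through an optional manual-override
#' table, then the primary mapping table; resolved codes are truncated to
#' their first three characters (codes shorter than three characters are
#' kept as-is; no padding).  Hospital codes that are already ICD-like can
#' be passed with `table = NULL`, in which case they are truncated only.
#' Events with unresolvable raw codes are dropped and reported.
#'
#' @param events data frame with columns `patient_id`, `dimension`,
#'   `raw_code`, `event_date`; all rows must be in the observation or
#'   hospitalisation dimension.
#' @param table mapping data frame (`source_code`, `target_code`) or
#'   `NULL` for truncation-only.
#' @param manual optional override table applied before `table`.
#' @param truncate_to number of leading characters retained (default 3).
#' @return A `mapped_events` object: `$events` (with `harmonized_code`
#'   replacing `raw_code`) and `$unmapped` (code, n; sorted by occurrence
#'   count, descending).
#' @export
map_and_truncate_observations <- function(events, table = NULL,
                                          manual = NULL, truncate_to = 3L) {
  stopifnot(all(events$dimension %in% c("observation", "hospitalisation")))
  check_mapping_table(table)
  check_mapping_table(manual, "manual override table")
  if (!is.null(table) && nrow(table) == 0L && nrow(events) > 0L)
    warning("empty mapping table: all events reported as unmapped")

  target <- lookup(events$raw_code, manual)
  if (is.null(table)) {
    # already in the harmonized vocabulary; truncate only
    target[is.na(target)] <- events$raw_code[is.na(target)]
  } else {
    miss <- is.na(target)
    target[miss] <- lookup(events$raw_code[miss], table)
  }
  ok <- !is.na(target)
  mapped <- events[ok, c("patient_id", "dimension", "event_date"),
                   drop = FALSE]
  mapped$harmonized_code <- substr(target[ok], 1L, truncate_to)
  mapped <- mapped[, c("patient_id", "dimension", "harmonized_code",
                       "event_date")]
  new_mapped_events(mapped, events$raw_code[!ok])
}

#' Map prescription codes to formulary paragraphs
#'
#' Raw drug codes are resolved through an optional manual-override table,
#' then the primary table; remaining misses consult the fallback table,
#' whose values are chapter strings of which the first six characters are
#' used.  Remaining misses are dropped and reported.
#'
#' @param events data frame of prescription-dimension events.
#' @param table primary mapping table (`source_code`, `target_code`).
#' @param fallback_table fallback table; its target codes are reduced to
#'   their first six characters.
#' @param manual optional override table applied first.
#' @return A `mapped_events` object.
#' @export
map_prescriptions <- function(events, table, fallback_table = NULL,
                              manual = NULL) {
  stopifnot(all(events$dimension == "prescription"))
  check_mapping_table(table)
  check_mapping_table(fallback_table, "fallback table")
  check_mapping_table(manual, "manual override table")
  if (!is.null(table) && nrow(table) == 0L && nrow(events) > 0L &&
      (is.null(fallback_table) || nrow(fallback_table) == 0L))
    warning("empty mapping table: all events reported as unmapped")

  target <- lookup(events$raw_code, manual)
  miss <- is.na(target)
  target[miss] <- lookup(events$raw_code[miss], table)
  miss <- is.na(target)
  fb <- lookup(events$raw_code[miss], fallback_table)
  target[miss] <- ifelse(is.na(fb), NA_character_, substr(fb, 1L, 6L))

  ok <- !is.na(target)
  mapped <- events[ok, c("patient_id", "dimension", "event_date"),
                   drop = FALSE]
  mapped$harmonized_code <- target[ok]
  mapped <- mapped[, c("patient_id", "dimension", "harmonized_code",
                       "event_date")]
  new_mapped_events(mapped, events$raw_code[!ok])
}

#' Remove exposure- and outcome-defining codes from the candidate pool
#'
#' Drops every event whose harmonized code appears in the exclusion list
#' (drug classes used to define the treatment groups; the ICD chapter used
#' to define the outcome).  Codes used to define the prespecified
#' covariates are deliberately not excluded.
#'
#' @param mapped a `mapped_events` object or a mapped events data frame.
#' @param exclusion_spec character vector of harmonized codes to remove.
#' @return Same type as `mapped`, with excluded rows removed.
#' @export
apply_code_exclusions <- function(mapped, exclusion_spec) {
  if (inherits(mapped, "mapped_events")) {
    mapped$events <- apply_code_exclusions(mapped$events, exclusion_spec)
    return(mapped)
  }
  stopifnot("harmonized_code" %in% names(mapped))
  if (length(exclusion_spec) == 0L) return(mapped)
  out <- mapped[!(mapped$harmonized_code %in% exclusion_spec), ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine mapped event tables across dimensions
#'
#' @param ... `mapped_events` objects.
#' @return A single `mapped_events` object with row-bound events and a
#'   merged unmapped report (re-sorted by occurrence count).
#' @export
combine_mapped_events <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "mapped_events")))
  ev <- do.call(rbind, lapply(parts, `[[`, "events"))
  un <- do.call(rbind, lapply(parts, `[[`, "unmapped"))
  out <- new_mapped_events(ev, character())
  if (nrow(un)) {
    agg <- stats::aggregate(n ~ code, data = un, FUN = sum)
    agg <- agg[order(-agg$n, agg$code), , drop = FALSE]
    rownames(agg) <- NULL
    out$unmapped <- agg
  }
  out
}
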