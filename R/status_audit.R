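#' Audit one record for a status/completion conflict
#'
#' A record is *conflicting* when it declares an open recruitment status
#' ("Recruiting" or "Not yet recruiting") while its stated study
#' completion date lies entirely in the past relative to the reference
#' date. Fuzzy completion dates are compared under the latest-day
#' interpretation ([latest_day()]): a month or year only counts as past
#' once all of it has elapsed, which prevents false conflict flags.
#'
#' @param record A [trial_record()].
#' @param reference_date Day-precision `Date` playing the role of "today"
#'   (the corpus retrieval date).
#' @return One-row `data.frame`: `nct_id`, `is_open_status`,
#'   `completion_in_past` (`NA` when no completion date), `conflicting`,
#'   `days_since_update`.
#' @export
flag_conflict <- function(record, reference_date) {
  stopifnot(inherits(record, "trial_record"))
  reference_date <- as.Date(reference_date)
  is_open <- record$overall_status %in% open_statuses()
  in_past <- if (is.null(record$completion_date)) NA else
    latest_day(record$completion_date) < reference_date
  data.frame(
    nct_id = record$nct_id,
    is_open_status = is_open,
    completion_in_past = in_past,
    conflicting = is_open && isTRUE(in_past),
    days_since_update = days_since_update(record, reference_date),
    stringsAsFactors = FALSE)
}

#' Days elapsed since a record's last update
#'
#' Staleness of a record: reference date minus the latest-day reading of
#' the last-update date, clamped at zero when the fuzzy update period
#' straddles the reference date. A last update whose *earliest* possible
#' day lies after the reference date signals a corrupted corpus and is an
#' error.
#'
#' @inheritParams flag_conflict
#' @return Nonnegative integer number of days.
#' @export
days_since_update <- function(record, reference_date) {
  stopifnot(inherits(record, "trial_record"))
  reference_date <- as.Date(reference_date)
  if (earliest_day(record$last_update) > reference_date)
    stop_ctg(sprintf("%s: last_update after reference date", record$nct_id),
             "ctg_staleness_error")
  max(0L, as.integer(reference_date - latest_day(record$last_update)))
}

#' Audit every record in a corpus
#'
#' Applies [flag_conflict()] to each record using its domain's reference
#' date from the corpus manifest.
#'
#' @param corpus A [ctg_corpus()].
#' @return `data.frame` with one row per record (columns of
#'   [flag_conflict()] plus `domain_tag`).
#' @export
audit_corpus_status <- function(corpus) {
  stopifnot(inherits(corpus, "ctg_corpus"))
  rows <- lapply(corpus$records, function(r) {
    out <- flag_conflict(r, reference_date_for(corpus, r$domain_tag))
    out$domain_tag <- r$domain_tag
    out
  })
  do.call(rbind, rows)
}

#' Per-domain conflict table
#'
#' Counts and whole-percent shares of conflicting records per domain plus
#' an overall row (percent rounding: half away from zero).
#'
#' @param x A [ctg_corpus()] or the `data.frame` from
#'   [audit_corpus_status()].
#' @return `data.frame` with columns `domain_tag`, `n_trials`,
#'   `n_conflicting`, `percent_conflicting`; last row is `overall`.
#' @export
conflict_table <- function(x) {
  audit <- if (inherits(x, "ctg_corpus")) audit_corpus_status(x) else x
  doms <- sort(unique(audit$domain_tag))
  rows <- lapply(doms, function(d) {
    sub <- audit[audit$domain_tag == d, ]
    data.frame(domain_tag = d, n_trials = nrow(sub),
               n_conflicting = sum(sub$conflicting),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(domain_tag = "overall",
                               n_trials = sum(tab$n_trials),
                               n_conflicting = sum(tab$n_conflicting)))
  tab$percent_conflicting <- percent_of(tab$n_conflicting, tab$n_trials)
  tab
}
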