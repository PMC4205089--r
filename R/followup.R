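#' Reference point for distance ordering
#'
#' Contact plans order a trial's recruitment locations by great-circle
#' distance to Boston, Massachusetts; these are the fixed coordinates
#' used for that reference.
#'
#' @return Named numeric vector `c(lat = , lon = )`.
#' @export
boston_reference <- function() c(lat = 42.3601, lon = -71.0589)

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b Coordinates as `c(lat, lon)` in decimal degrees (named or
#'   positional, latitude first).
#' @return Distance in kilometers.
#' @export
haversine_km <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (abs(a[1]) > 90 || abs(b[1]) > 90 || abs(a[2]) > 180 || abs(b[2]) > 180)
    stop_ctg("coordinates out of range", "ctg_coord_error")
  # geosphere expects lon/lat ordering
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = 6371000) / 1000
}

#' Trials eligible for follow-up verification
#'
#' The verification subset mirrors the audit's sampling frame: trials
#' with at least one location in the United States and an open
#' recruitment status ("Recruiting" or "Not yet recruiting").
#'
#' @param corpus A [ctg_corpus()].
#' @return List of [trial_record()]s.
#' @export
eligible_for_followup <- function(corpus) {
  Filter(function(r) {
    r$overall_status %in% open_statuses() &&
      any(vapply(r$locations, function(l)
        grepl("united states", tolower(l$country)), logical(1)))
  }, corpus$records)
}

#' Last-update-stratified sample of trials
#'
#' Orders the eligible trials by their last-update date (latest-day
#' reading, `nct_id` as tiebreak), splits the ordered list into
#' contiguous segments of as-equal-as-possible size (remainder to the
#' earliest segments), and samples without replacement within each
#' segment; segments smaller than the per-segment target are taken
#' whole. The stratification guarantees the sample spans the full
#' staleness range.
#'
#' @param trials List of eligible [trial_record()]s (pre-filtered, e.g.
#'   by [eligible_for_followup()]).
#' @param per_segment Trials drawn per segment (default 10).
#' @param segments Number of segments (default 4).
#' @param seed Integer seed; the plan is deterministic given it.
#' @return Object of class `sampling_plan`: `eligible_ids` (ordered),
#'   `segment_sizes`, `sampled_ids`, `per_segment`, `segments`, `seed`.
#' @export
stratified_sample <- function(trials, per_segment = 10, segments = 4, seed = 1L) {
  if (length(trials) == 0L)
    return(structure(list(eligible_ids = character(0),
                          segment_sizes = integer(segments),
                          sampled_ids = character(0),
                          per_segment = per_segment, segments = segments,
                          seed = seed),
                     class = "sampling_plan"))
  ids <- vapply(trials, function(r) r$nct_id, character(1))
  upd <- as.Date(vapply(trials, function(r) as.character(latest_day(r$last_update)),
                        character(1)))
  ord <- order(upd, ids)
  ids <- ids[ord]
  n <- length(ids)
  base <- n %/% segments
  sizes <- rep(base, segments) + c(rep(1L, n %% segments),
                                   rep(0L, segments - n %% segments))
  bounds <- cumsum(sizes)
  starts <- c(1L, head(bounds, -1L) + 1L)
  sampled <- with_seed(seed, {
    unlist(lapply(seq_len(segments), function(k) {
      if (sizes[k] == 0L) return(character(0))
      seg <- ids[starts[k]:bounds[k]]
      if (length(seg) <= per_segment) seg
      else seg[sort(sample.int(length(seg), per_segment))]
    }))
  })
  structure(list(eligible_ids = ids, segment_sizes = sizes,
                 sampled_ids = sampled, per_segment = per_segment,
                 segments = segments, seed = seed),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan: %d eligible, segments %s, %d sampled (seed %s)>\n",
              length(x$eligible_ids), paste(x$segment_sizes, collapse = "/"),
              length(x$sampled_ids), format(x$seed)))
  invisible(x)
}

#' Build the contact plan for one trial
#'
#' Attempts are ordered: the three geographically closest locations that
#' carry any contact information (distance to the reference point,
#' locations without coordinates sorting last, stably), then the trial's
#' overall contact, then the backup contact. Entries without any contact
#' information are skipped, not counted. Each attempt carries the
#' per-location outreach budget of at most 3 phone calls and 1 email.
#'
#' @param record A [trial_record()].
#' @param reference_point `c(lat, lon)`; defaults to [boston_reference()].
#' @return `data.frame` with one row per attempt: `attempt`, `source`,
#'   `name`, `phone`, `email`, `distance_km`, `max_calls`, `max_emails`.
#'   Zero rows when the record carries no contact information anywhere.
#' @export
build_contact_plan <- function(record, reference_point = boston_reference()) {
  stopifnot(inherits(record, "trial_record"))
  locs <- record$locations
  has_contact <- vapply(locs, function(l) !is.null(l$contact), logical(1))
  locs <- locs[has_contact]
  if (length(locs)) {
    dist <- vapply(locs, function(l) {
      if (is.null(l$latitude) || is.null(l$longitude)) Inf
      else haversine_km(reference_point, c(l$latitude, l$longitude))
    }, numeric(1))
    locs <- locs[order(dist)]  # stable: coordinate-less (Inf) keep input order
    dist <- sort(dist)
    keep <- seq_len(min(3L, length(locs)))
    locs <- locs[keep]; dist <- dist[keep]
  } else dist <- numeric(0)

  rows <- lapply(seq_along(locs), function(i) {
    ct <- locs[[i]]$contact
    data.frame(source = "location", name = ct$name,
               phone = ct$phone %||% NA_character_,
               email = ct$email %||% NA_character_,
               distance_km = dist[i], stringsAsFactors = FALSE)
  })
  for (src in c("overall", "backup")) {
    ct <- if (src == "overall") record$overall_contact else record$backup_contact
    if (!is.null(ct))
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, name = ct$name, phone = ct$phone %||% NA_character_,
        email = ct$email %||% NA_character_, distance_km = NA_real_,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(attempt = integer(0), source = character(0),
                      name = character(0), phone = character(0),
                      email = character(0), distance_km = numeric(0),
                      max_calls = integer(0), max_emails = integer(0),
                      stringsAsFactors = FALSE))
  plan <- do.call(rbind, rows)
  plan <- cbind(attempt = seq_len(nrow(plan)), plan,
                max_calls = 3L, max_emails = 1L)
  plan
}

#' Classify follow-up responses into the four outcome categories
#'
#' The first informative response decides: a confirmed-open reply yields
#' `open`, a confirmed-closed reply yields `closed` (with the reported
#' close date). A refusal with no later informative response yields
#' `dont_know`; no responses at all — including trials with no contact
#' information anywhere — yield `no_answer`.
#'
#' @param responses Character vector of attempt results, in attempt
#'   order; each one of `"confirmed_open"`, `"confirmed_closed"`,
#'   `"refused"`, `"unreachable"`. May be empty.
#' @param dates Optional list of [fuzzy_date()]s (or `NULL`s) aligned
#'   with `responses`; the close date is taken from the deciding
#'   response.
#' @return List: `category`, `close_date` (only for `closed`),
#'   `attempts_used`.
#' @export
classify_outcome <- function(responses, dates = NULL) {
  stopifnot(all(responses %in% c("confirmed_open", "confirmed_closed",
                                 "refused", "unreachable")))
  refused <- FALSE
  for (i in seq_along(responses)) {
    if (responses[i] == "confirmed_open")
      return(list(category = "open", close_date = NULL, attempts_used = i))
    if (responses[i] == "confirmed_closed")
      return(list(category = "closed",
                  close_date = if (!is.null(dates)) dates[[i]] else NULL,
                  attempts_used = i))
    if (responses[i] == "refused") refused <- TRUE
  }
  list(category = if (refused) "dont_know" else "no_answer",
       close_date = NULL, attempts_used = length(responses))
}

#' Tabulate follow-up outcomes
#'
#' Per-domain and overall counts of the four verification categories,
#' with whole-percent overall shares. Trials flagged as dropped (e.g.
#' completed between corpus creation and contact download) are excluded
#' from the denominator and reported in `n_dropped`.
#'
#' @param outcomes `data.frame` with columns `nct_id`, `domain_tag`,
#'   `category`, and optionally a logical `dropped`.
#' @return `data.frame`: per-domain rows plus `overall`, with counts per
#'   category, `n`, `n_dropped`, and `percent_*` columns on the overall
#'   denominator.
#' @export
followup_table <- function(outcomes) {
  cats <- c("open", "closed", "dont_know", "no_answer")
  stopifnot(all(outcomes$category %in% cats))
  if (is.null(outcomes$dropped)) outcomes$dropped <- FALSE
  kept <- outcomes[!outcomes$dropped, ]
  doms <- sort(unique(outcomes$domain_tag))
  rows <- lapply(c(doms, "overall"), function(d) {
    sub <- if (d == "overall") kept else kept[kept$domain_tag == d, ]
    subd <- if (d == "overall") outcomes else outcomes[outcomes$domain_tag == d, ]
    counts <- vapply(cats, function(cc) sum(sub$category == cc), integer(1))
    cbind(data.frame(domain_tag = d, n = nrow(sub),
                     n_dropped = sum(subd$dropped), stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(counts, paste0("n_", cats)))),
          as.data.frame(as.list(setNames(percent_of(counts, nrow(sub)),
                                         paste0("percent_", cats)))))
  })
  do.call(rbind, rows)
}
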