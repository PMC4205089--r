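#' Load the synthetic criteria template bank
#'
#' Templates are written against the *category definitions*, while the
#' detectors are written against the rule pack — the two live in
#' separate data files so their agreement, asserted in the test suite,
#' is a real drift check rather than a tautology.
#'
#' @param path Path to a template-bank JSON; default is the bank bundled
#'   with the package.
#' @return A list with class `template_bank`.
#' @export
load_template_bank <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "criteria_templates.json", package = "ctgaudit")
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "template_bank")
}

fill_template <- function(tpl, lexicons) {
  slots <- regmatches(tpl, gregexpr("\\{[A-Z]+\\}", tpl))[[1]]
  for (s in unique(slots)) {
    key <- gsub("[{}]", "", s)
    vals <- lexicons[[key]]
    if (is.null(vals)) stop_ctg(paste("unknown template slot", s), "ctg_spec_error")
    # each occurrence gets its own draw
    while (grepl(s, tpl, fixed = TRUE))
      tpl <- sub(s, vals[sample.int(length(vals), 1L)], tpl, fixed = TRUE)
  }
  tpl
}

#' Default corpus specification
#'
#' The generator's parameters mirror the audit conditions of a
#' four-domain registry snapshot: per-domain trial counts and retrieval
#' (reference) dates, conflict prevalences, eligibility-format mixes,
#' per-category barrier prevalences, and per-domain criterion totals.
#' Planting is variance-controlled: each prevalence is realized as an
#' exact count (rounded half away from zero, largest-remainder for the
#' format mix) assigned to uniformly random trials, so a default corpus
#' reproduces the planted percentages exactly at the planted n.
#'
#' The date model couples record staleness to data quality: conflicting
#' trials are drawn from the stale last-update regime far more often than
#' clean ones, and truly closed trials are mostly stale — the couplings
#' the recency comparisons are designed to detect.
#'
#' @param seed Integer seed (default 42); all generator randomness flows
#'   from it.
#' @return A list with class `corpus_spec`.
#' @export
default_corpus_spec <- function(seed = 42L) {
  spec <- list(
    domains = data.frame(
      domain_tag = c("gleevec", "cataract", "neuroblastoma", "rheumatoid_arthritis"),
      n_trials = c(98L, 113L, 124L, 102L),
      reference_date = as.Date(c("2013-06-06", "2013-06-12",
                                 "2013-06-20", "2013-07-05")),
      conflict_prevalence = c(0.14, 0.46, 0.15, 0.19),
      p_suggested = c(0.88, 0.98, 0.79, 0.98),
      p_extended = c(0.09, 0.01, 0.18, 0.00),
      criteria_total = c(1641L, 1163L, 1979L, 1167L),
      p_subpopulation = c(0.42, 0.12, 0.35, 0.17),
      p_lab = c(0.70, 0.48, 0.73, 0.45),
      p_temporal = c(0.78, 0.32, 0.65, 0.64),
      p_patient = c(0.61, 0.54, 0.49, 0.47),
      stringsAsFactors = FALSE),
    date_model = list(
      fresh_shape = 1.5, fresh_scale = 40,   # mean ~60 days since update
      stale_shape = 2, stale_scale = 350,    # mean ~700 days since update
      p_stale_given_conflict = 0.9, p_stale_given_clean = 0.2,
      p_closed_given_stale = 0.75, p_closed_given_fresh = 0.12),
    contact_model = list(
      p_location_contact = 0.7, p_overall_contact = 0.95,
      p_backup_contact = 0.5, mean_locations = 2.5, p_us_location = 0.85),
    criteria_dispersion = 6,
    p_nested_subpopulation = 0.35,
    p_negated_distractor = 0.3,
    seed = as.integer(seed))
  validate_corpus_spec(spec)
  structure(spec, class = "corpus_spec")
}

validate_corpus_spec <- function(spec) {
  d <- spec$domains
  probs <- c(d$conflict_prevalence, d$p_suggested, d$p_extended,
             d$p_subpopulation, d$p_lab, d$p_temporal, d$p_patient)
  bad <- character(0)
  if (any(probs < 0 | probs > 1)) bad <- c(bad, "prevalences must be in [0, 1]")
  if (any(d$p_suggested + d$p_extended > 1)) bad <- c(bad, "format mix exceeds 1")
  if (any(d$n_trials < 1)) bad <- c(bad, "n_trials must be >= 1")
  if (any(d$criteria_total < d$n_trials)) bad <- c(bad, "criteria_total below one per trial")
  if (length(bad))
    stop_ctg(paste("invalid corpus spec:", paste(bad, collapse = "; ")),
             "ctg_spec_error")
  invisible(spec)
}

# ---- pieces of the generator ------------------------------------------

.us_box <- list(lat = c(25.5, 48.5), lon = c(-123.5, -68.0))
.eu_box <- list(lat = c(43.0, 58.0), lon = c(-5.0, 20.0))
.cities_us <- c("Boston", "New York", "Chicago", "Houston", "Seattle",
                "Denver", "Atlanta", "Portland", "Baltimore", "Cleveland")
.cities_eu <- c("Berlin", "Paris", "Madrid", "Milan", "Amsterdam", "Vienna")
.countries_eu <- c("Germany", "France", "Spain", "Italy", "Netherlands", "Austria")
.surnames <- c("Nguyen", "Okafor", "Silva", "Hansen", "Kim", "Rossi",
               "Dubois", "Yamada", "Novak", "Miller")

rand_contact <- function() {
  contact_info(
    name = paste("Dr.", sample(.surnames, 1L)),
    phone = sprintf("(%03d) 555-%04d", sample(200:989, 1L), sample(0:9999, 1L)),
    email = sprintf("coord%04d@example.org", sample(0:9999, 1L)))
}

rand_location <- function(cm) {
  us <- runif(1) < cm$p_us_location
  box <- if (us) .us_box else .eu_box
  trial_location(
    facility = sprintf("%s Medical Center",
                       sample(if (us) .cities_us else .cities_eu, 1L)),
    city = sample(if (us) .cities_us else .cities_eu, 1L),
    country = if (us) "United States" else sample(.countries_eu, 1L),
    latitude = round(runif(1, box$lat[1], box$lat[2]), 4),
    longitude = round(runif(1, box$lon[1], box$lon[2]), 4),
    contact = if (runif(1) < cm$p_location_contact) rand_contact() else NULL)
}

# month arithmetic on a Date, returning a month-precision fuzzy date
shift_month <- function(date, k) {
  lt <- as.POSIXlt(date)
  m0 <- (lt$year + 1900L) * 12L + lt$mon + k
  fuzzy_date(m0 %/% 12L, m0 %% 12L + 1L, precision = "month")
}

rand_completion <- function(ref, conflict) {
  if (conflict) {
    u <- runif(1)
    if (u < 0.8) shift_month(ref, -sample(1:18, 1L))
    else if (u < 0.9) {
      d <- ref - sample(30:500, 1L)
      lt <- as.POSIXlt(d)
      fuzzy_date(lt$year + 1900L, lt$mon + 1L, lt$mday, "day")
    } else fuzzy_date(as.POSIXlt(ref)$year + 1900L - sample(1:3, 1L),
                      precision = "year")
  } else {
    if (runif(1) < 0.3) return(NULL)
    if (runif(1) < 0.85) shift_month(ref, sample(0:36, 1L))
    else fuzzy_date(as.POSIXlt(ref)$year + 1900L + sample(0:2, 1L),
                    precision = "year")
  }
}

as_day_fuzzy <- function(date) {
  lt <- as.POSIXlt(date)
  fuzzy_date(lt$year + 1900L, lt$mon + 1L, lt$mday, "day")
}

# distribute the domain's exact criterion total over its segmentable
# trials: overdispersed counts (negative binomial), floors respected,
# then nudged until the sum matches
criteria_counts <- function(n, total, mins, dispersion) {
  if (n == 0L) return(integer(0))
  mu <- max(1, total / n)
  m <- pmin(pmax(rnbinom(n, size = dispersion, mu = mu), mins), 60L)
  while (sum(m) > total) {
    cand <- which(m > pmax(mins, 1L))
    if (!length(cand)) break
    idx <- cand[sample.int(length(cand), 1L)]
    m[idx] <- m[idx] - 1L
  }
  while (sum(m) < total) {
    i <- sample.int(n, 1L)
    m[i] <- m[i] + 1L
  }
  m
}

#' Render an eligibility textblock from category labels
#'
#' Builds the text of one trial's eligibility criteria in the requested
#' macro-format. Each labeled cell is rendered from a category-unambiguous
#' template with randomized slot fills; `plain` cells use distractor
#' templates that trip no detector; `subpopulation_nested` renders a
#' subgroup-header parent with an indented child bullet (suggested format
#' only). `prose` produces an unstructured paragraph for
#' neither-format trials.
#'
#' @param labels Character vector of cell categories, in order: any of
#'   `"plain"`, `"plain_negated"`, `"temporal"`, `"lab"`,
#'   `"subpopulation"`, `"subpopulation_nested"`, `"patient"`, `"prose"`.
#' @param format One of `"suggested"`, `"extended"`, `"neither"`.
#' @param bank A [load_template_bank()] result.
#' @param n_exclusion For the suggested format, how many trailing cells
#'   render under "Exclusion Criteria" (0 = inclusion-only).
#' @return List: `text` (the textblock) and `cells` (`data.frame` of
#'   `category`, `text` per rendered criterion; a nested cell yields two
#'   rows, `subpopulation_parent` and `subpopulation_child`).
#' @export
render_criteria <- function(labels, format = c("suggested", "extended", "neither"),
                            bank = load_template_bank(), n_exclusion = 0L) {
  format <- match.arg(format)
  lex <- bank$lexicons
  render_cell <- function(label) {
    switch(label,
      plain = data.frame(category = "plain",
                         text = fill_template(sample(bank$distractor, 1L), lex),
                         stringsAsFactors = FALSE),
      plain_negated = data.frame(category = "plain_negated",
                                 text = fill_template(sample(bank$distractor_negated, 1L), lex),
                                 stringsAsFactors = FALSE),
      temporal = data.frame(category = "temporal",
                            text = fill_template(sample(bank$temporal, 1L), lex),
                            stringsAsFactors = FALSE),
      lab = data.frame(category = "lab",
                       text = fill_template(sample(bank$lab, 1L), lex),
                       stringsAsFactors = FALSE),
      subpopulation = data.frame(category = "subpopulation",
                                 text = fill_template(sample(bank$subpopulation, 1L), lex),
                                 stringsAsFactors = FALSE),
      subpopulation_nested = data.frame(
        category = c("subpopulation_parent", "subpopulation_child"),
        text = c(fill_template(bank$subpopulation_nested$parent, lex),
                 fill_template(sample(bank$subpopulation_nested$children, 1L), lex)),
        stringsAsFactors = FALSE),
      patient = data.frame(category = "patient",
                           text = fill_template(sample(bank$patient, 1L), lex),
                           stringsAsFactors = FALSE),
      prose = data.frame(category = "prose",
                         text = fill_template(sample(bank$prose, 1L), lex),
                         stringsAsFactors = FALSE),
      stop_ctg(paste("unknown cell label", label), "ctg_spec_error"))
  }
  cells <- do.call(rbind, lapply(labels, render_cell))

  bullet <- function(row) {
    if (row$category == "subpopulation_child") paste0("      -  ", row$text)
    else paste0("  -  ", row$text)
  }
  if (format == "suggested") {
    n <- nrow(cells)
    n_exclusion <- min(n_exclusion, n - 1L)
    incl <- cells[seq_len(n - n_exclusion), , drop = FALSE]
    excl <- if (n_exclusion > 0L) cells[(n - n_exclusion + 1L):n, , drop = FALSE] else NULL
    lines <- c("Inclusion Criteria:", "",
               vapply(seq_len(nrow(incl)), function(i) bullet(incl[i, ]), character(1)))
    if (!is.null(excl))
      lines <- c(lines, "", "Exclusion Criteria:", "",
                 vapply(seq_len(nrow(excl)), function(i) bullet(excl[i, ]), character(1)))
  } else if (format == "extended") {
    topics <- c("DISEASE CHARACTERISTICS:", "PATIENT CHARACTERISTICS:",
                "PRIOR CONCURRENT THERAPY:")
    k <- max(2L, min(3L, nrow(cells)))
    assign_topic <- rep(seq_len(k), length.out = nrow(cells))
    ord <- order(assign_topic)  # stable: cells emitted in rendered order
    cells <- cells[ord, , drop = FALSE]
    rownames(cells) <- NULL
    assign_topic <- assign_topic[ord]
    lines <- character(0)
    for (t in seq_len(k)) {
      rows <- cells[assign_topic == t, , drop = FALSE]
      lines <- c(lines, if (t > 1L) "", topics[t], "",
                 vapply(seq_len(nrow(rows)), function(i) bullet(rows[i, ]), character(1)))
    }
  } else {
    lines <- cells$text  # bare sentences/paragraphs, no markers, no headings
  }
  list(text = paste(lines, collapse = "\n"), cells = cells)
}

# draw a trial's cell labels from its planted trial-level barrier flags
trial_cell_labels <- function(m, flags, format, nested, p_neg) {
  planted <- character(0)
  if (flags[["subpopulation"]])
    planted <- c(planted, if (nested) "subpopulation_nested" else "subpopulation")
  if (flags[["lab"]]) planted <- c(planted, "lab")
  if (flags[["temporal"]]) planted <- c(planted, "temporal")
  if (flags[["patient"]]) planted <- c(planted, "patient")
  n_cells <- m - (flags[["subpopulation"]] && nested)  # nested pair = 2 criteria, 1 cell
  fillers <- rep("plain", max(0L, n_cells - length(planted)))
  if (format == "extended" && length(fillers))
    fillers[runif(length(fillers)) < p_neg] <- "plain_negated"
  labs <- c(planted, fillers)
  labs[sample.int(length(labs))]
}

#' Generate a synthetic registry corpus with planted ground truth
#'
#' Produces a corpus of fully populated trial records — statuses, fuzzy
#' dates, eligibility textblocks rendered from the template bank,
#' locations with coordinates, contacts — together with the ground-truth
#' labels the generator planted, so every pipeline stage can be scored
#' against known answers. Deterministic given `spec$seed`.
#'
#' Conflicts are realized structurally: a conflicting trial gets an open
#' status and a completion date strictly in the past (latest-day
#' reading) relative to its domain's reference date; clean trials get a
#' future or absent completion date. Criterion totals are exact per
#' domain, distributed over format-segmentable trials.
#'
#' @param spec A [default_corpus_spec()] (or a modified copy).
#' @return List: `corpus` (a [ctg_corpus()]) and `truth` (list with
#'   `trials` and `criteria` data frames).
#' @export
generate_corpus <- function(spec = default_corpus_spec()) {
  validate_corpus_spec(spec)
  bank <- load_template_bank()
  dm <- spec$date_model; cm <- spec$contact_model
  with_seed(spec$seed, {
    n_all <- sum(spec$domains$n_trials)
    nct_ids <- sprintf("NCT%08d", sample.int(99999999L, n_all))
    id_i <- 0L
    records <- list(); truth_rows <- list(); crit_rows <- list()

    for (di in seq_len(nrow(spec$domains))) {
      d <- spec$domains[di, ]
      n <- d$n_trials
      ref <- d$reference_date

      conflict <- logical(n)
      conflict[sample.int(n, round_half_away(n * d$conflict_prevalence))] <- TRUE
      fmt_counts <- apportion_counts(n, c(d$p_suggested, d$p_extended,
                                          1 - d$p_suggested - d$p_extended))
      format_lab <- sample(rep(c("suggested", "extended", "neither"), fmt_counts))
      flags <- sapply(c(sub = d$p_subpopulation, lab = d$p_lab,
                        tem = d$p_temporal, pat = d$p_patient), function(p) {
        f <- logical(n); f[sample.int(n, round_half_away(n * p))] <- TRUE; f
      })
      colnames(flags) <- c("subpopulation", "lab", "temporal", "patient")

      stale <- runif(n) < ifelse(conflict, dm$p_stale_given_conflict,
                                 dm$p_stale_given_clean)
      lag <- ifelse(stale,
                    rgamma(n, shape = dm$stale_shape, scale = dm$stale_scale),
                    rgamma(n, shape = dm$fresh_shape, scale = dm$fresh_scale))
      closed <- runif(n) < ifelse(stale, dm$p_closed_given_stale,
                                  dm$p_closed_given_fresh)
      nested <- flags[, "subpopulation"] & format_lab == "suggested" &
        runif(n) < spec$p_nested_subpopulation

      seg <- format_lab != "neither"
      mins <- rowSums(flags) + nested
      mins[format_lab == "extended"] <- pmax(mins[format_lab == "extended"], 2L)
      mins <- pmax(mins, 1L)
      m <- integer(n)
      m[seg] <- criteria_counts(sum(seg), d$criteria_total, mins[seg],
                                spec$criteria_dispersion)

      for (i in seq_len(n)) {
        id_i <- id_i + 1L
        nct <- nct_ids[id_i]
        last_upd <- ref - round(lag[i])
        first_rec <- last_upd - round(rgamma(1, shape = 2, scale = 200)) - 30L

        if (seg[i]) {
          labels <- trial_cell_labels(m[i], flags[i, ], format_lab[i],
                                      nested[i], spec$p_negated_distractor)
          n_excl <- if (format_lab[i] == "suggested")
            min(sum(labels == "plain"), round(m[i] * 0.3)) else 0L
          # exclusion cells must be distractors: move plains to the tail
          if (n_excl > 0L) {
            plains <- which(labels == "plain")
            tail_ids <- plains[(length(plains) - n_excl + 1L):length(plains)]
            labels <- c(labels[-tail_ids], labels[tail_ids])
          }
          rend <- render_criteria(labels, format_lab[i], bank, n_exclusion = n_excl)
        } else {
          labels <- trial_cell_labels(
            max(1L, sum(flags[i, ])), flags[i, ], "neither", FALSE, 0)
          labels[labels == "plain"] <- "prose"
          labels <- c(labels, "prose")
          rend <- render_criteria(labels, "neither", bank)
        }

        n_loc <- 1L + rpois(1, max(0, cm$mean_locations - 1))
        locs <- lapply(seq_len(n_loc), function(j) rand_location(cm))
        status <- if (runif(1) < 0.9) "recruiting" else "not_yet_recruiting"

        records[[id_i]] <- trial_record(
          nct_id = nct, domain_tag = d$domain_tag,
          overall_status = status,
          first_received = as_day_fuzzy(first_rec),
          last_update = as_day_fuzzy(last_upd),
          completion_date = rand_completion(ref, conflict[i]),
          eligibility_text = rend$text,
          minimum_age = "18 Years", maximum_age = NULL,
          gender = "all", healthy_volunteers = FALSE,
          locations = locs,
          overall_contact = if (runif(1) < cm$p_overall_contact) rand_contact() else NULL,
          backup_contact = if (runif(1) < cm$p_backup_contact) rand_contact() else NULL)

        truth_rows[[id_i]] <- data.frame(
          nct_id = nct, domain_tag = d$domain_tag,
          true_open = !closed[i], conflict = conflict[i], stale = stale[i],
          format = format_lab[i],
          subpopulation = flags[i, "subpopulation"], lab = flags[i, "lab"],
          temporal = flags[i, "temporal"], patient = flags[i, "patient"],
          n_criteria = if (seg[i]) m[i] else 0L,
          stringsAsFactors = FALSE)
        cr <- rend$cells
        cr$nct_id <- nct
        cr$domain_tag <- d$domain_tag
        cr$segmentable <- seg[i]
        crit_rows[[id_i]] <- cr
      }
    }
    refs <- setNames(spec$domains$reference_date, spec$domains$domain_tag)
    truth_crit <- do.call(rbind, crit_rows)
    rownames(truth_crit) <- NULL
    list(corpus = ctg_corpus(records, refs,
                             provenance = sprintf("synthetic corpus (seed %d)", spec$seed)),
         truth = list(trials = do.call(rbind, truth_rows), criteria = truth_crit))
  })
}

#' Default follow-up simulation parameters
#'
#' `p_reachable` is a per-trial reachability: with probability
#' `1 - p_reachable` (default 0.31) every attempt in a trial's contact
#' plan goes unanswered. Reached coordinators refuse (or do not know the
#' status) with probability `p_refuse`; otherwise they answer with
#' probability `p_knows`, reporting the trial's true status.
#'
#' @param p_reachable,p_refuse,p_knows Probabilities.
#' @return Named list.
#' @export
followup_params <- function(p_reachable = 0.69, p_refuse = 0.03, p_knows = 1.0) {
  p <- list(p_reachable = p_reachable, p_refuse = p_refuse, p_knows = p_knows)
  if (any(unlist(p) < 0 | unlist(p) > 1))
    stop_ctg("follow-up probabilities must be in [0, 1]", "ctg_spec_error")
  p
}

#' Simulate phone/email follow-up responses
#'
#' Stands in for real outreach: for each sampled trial, draws whether
#' anyone was reachable, at which attempt of the contact plan, and
#' whether the respondent refused or answered; informative answers
#' report the trial's planted true status (closed trials report a close
#' date). Deterministic given `seed`.
#'
#' @param corpus A [ctg_corpus()].
#' @param truth The `truth` element of [generate_corpus()] output.
#' @param sampled_ids Trials to contact (e.g. `sampled_ids` of a
#'   [stratified_sample()] plan, possibly concatenated across domains).
#' @param params A [followup_params()] list.
#' @param seed Integer seed.
#' @return `data.frame` of responses: `nct_id`, `attempt`, `result`,
#'   `date` (registry date string for confirmed closures, else `NA`).
#'   Trials with an empty contact plan contribute no rows.
#' @export
simulate_followup <- function(corpus, truth, sampled_ids,
                              params = followup_params(), seed = 1L) {
  recs <- setNames(corpus$records,
                   vapply(corpus$records, function(r) r$nct_id, character(1)))
  open_by_id <- setNames(truth$trials$true_open, truth$trials$nct_id)
  with_seed(seed, {
    rows <- list()
    for (id in sampled_ids) {
      plan <- build_contact_plan(recs[[id]])
      n_att <- nrow(plan)
      if (n_att == 0L) next
      if (runif(1) >= params$p_reachable) {
        res <- rep("unreachable", n_att)
        dates <- rep(NA_character_, n_att)
      } else {
        hit <- sample.int(n_att, 1L)
        res <- rep("unreachable", hit)
        dates <- rep(NA_character_, hit)
        if (runif(1) < params$p_refuse || runif(1) >= params$p_knows) {
          res[hit] <- "refused"
        } else if (open_by_id[[id]]) {
          res[hit] <- "confirmed_open"
        } else {
          res[hit] <- "confirmed_closed"
          dates[hit] <- format(shift_month(
            latest_day(recs[[id]]$last_update), sample(0:3, 1L)))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        nct_id = id, attempt = seq_along(res), result = res, date = dates,
        stringsAsFactors = FALSE)
    }
    if (!length(rows))
      return(data.frame(nct_id = character(0), attempt = integer(0),
                        result = character(0), date = character(0),
                        stringsAsFactors = FALSE))
    do.call(rbind, rows)
  })
}

#' Assemble follow-up outcomes from simulated (or recorded) responses
#'
#' Applies [classify_outcome()] per sampled trial; trials without any
#' response rows (no contact information anywhere) fall into
#' `no_answer`.
#'
#' @param responses Response table as from [simulate_followup()].
#' @param sampled_ids All sampled trial ids (defines the denominator).
#' @param corpus The audited [ctg_corpus()] (for domain tags).
#' @param dropped_ids Trials excluded before classification (e.g.
#'   completed between corpus creation and contact download); flagged
#'   `dropped` in the output.
#' @return `data.frame`: `nct_id`, `domain_tag`, `category`,
#'   `attempts_used`, `close_date`, `dropped`.
#' @export
followup_outcomes <- function(responses, sampled_ids, corpus,
                              dropped_ids = character(0)) {
  dom_by_id <- setNames(
    vapply(corpus$records, function(r) r$domain_tag, character(1)),
    vapply(corpus$records, function(r) r$nct_id, character(1)))
  rows <- lapply(sampled_ids, function(id) {
    sub <- responses[responses$nct_id == id, , drop = FALSE]
    sub <- sub[order(sub$attempt), , drop = FALSE]
    dates <- lapply(sub$date, function(dd)
      if (is.na(dd)) NULL else parse_fuzzy_date(dd))
    out <- classify_outcome(sub$result, dates)
    data.frame(nct_id = id, domain_tag = dom_by_id[[id]],
               category = out$category, attempts_used = out$attempts_used,
               close_date = if (is.null(out$close_date)) NA_character_ else
                 format(out$close_date),
               dropped = id %in% dropped_ids,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
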