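#' Load a barrier-detection rule pack
#'
#' The detectors' knowledge — time-unit and anchor patterns, analyte and
#' score lexicons, conditional markers, volition phrases — ships as data,
#' versioned and swappable, rather than being hard-coded. The version tag
#' is recorded in every annotation output for provenance.
#'
#' @param path Path to a rule-pack JSON document; default is the pack
#'   bundled with the package.
#' @return Object of class `rule_pack` with compiled alternation regexes.
#' @export
load_rule_pack <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "barrier_rules.json", package = "ctgaudit")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  alt <- function(patterns) paste0("(?:", paste(patterns, collapse = "|"), ")")
  rp <- list(
    version = raw$version,
    temporal = list(
      qty_unit_re = paste0(raw$temporal$quantity, "[ -]*", raw$temporal$units),
      anchors_re = alt(raw$temporal$anchors),
      exclusions_re = alt(raw$temporal$exclusions)),
    lab = list(
      term_re = paste0("\\b", alt(c(raw$lab$analytes, raw$lab$scores)), "\\b"),
      numeric_re = alt(raw$lab$numeric_contexts)),
    subpopulation = list(
      markers_re = alt(raw$subpopulation$markers),
      header_re = raw$subpopulation$subgroup_header),
    patient = list(phrases_re = alt(raw$patient$phrases)))
  # fail fast on a broken pack: every pattern must compile
  for (re in c(rp$temporal$qty_unit_re, rp$temporal$anchors_re,
               rp$temporal$exclusions_re, rp$lab$term_re, rp$lab$numeric_re,
               rp$subpopulation$markers_re, rp$subpopulation$header_re,
               rp$patient$phrases_re))
    grepl(re, "", perl = TRUE)
  structure(rp, class = "rule_pack")
}

# unicode comparators/symbols -> ASCII, character-for-character so match
# offsets computed on the normalized text remain valid on the original
normalize_criterion_text <- function(text) {
  tolower(gsub("[−–]", "-", chartr("≤≥×µ", "<>xu", text)))
}

match_span <- function(norm, re) {
  m <- regexpr(re, norm, perl = TRUE)
  if (m[1] == -1L) return(NULL)
  c(start = m[1], end = m[1] + attr(m, "match.length") - 1L)
}

evidence_row <- function(category, original, span) {
  data.frame(category = category,
             text = substr(original, span[["start"]], span[["end"]]),
             start = span[["start"]], end = span[["end"]],
             stringsAsFactors = FALSE)
}

empty_evidence <- function() {
  data.frame(category = character(0), text = character(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

age_excluded <- function(norm, rules) {
  grepl(rules$temporal$exclusions_re, norm, perl = TRUE)
}

#' Detect a temporal constraint in one criterion
#'
#' Fires when a quantity plus time unit ("2 weeks", "three months")
#' co-occurs with a temporal anchor (since, within, prior, before, at
#' least, no more than, comparators, ...). Age-bound criteria are
#' excluded: the registry carries age as a structured field.
#'
#' @param text One criterion's text.
#' @param rules A [load_rule_pack()] result.
#' @return `list(flag = logical, evidence = data.frame)`; evidence spans
#'   are 1-based character offsets into `text`.
#' @export
detect_temporal <- function(text, rules = load_rule_pack()) {
  norm <- normalize_criterion_text(text)
  if (age_excluded(norm, rules)) return(list(flag = FALSE, evidence = empty_evidence()))
  qty <- match_span(norm, rules$temporal$qty_unit_re)
  anc <- match_span(norm, rules$temporal$anchors_re)
  if (is.null(qty) || is.null(anc)) return(list(flag = FALSE, evidence = empty_evidence()))
  list(flag = TRUE,
       evidence = rbind(evidence_row("temporal", text, qty),
                        evidence_row("temporal", text, anc)))
}

#' Detect a laboratory value or medical score in one criterion
#'
#' Fires when an analyte or named-score lexicon term co-occurs with a
#' numeric context (comparator plus number, number plus unit token such
#' as mg/dL or /uL, or a bare numeric level for scores). Age-bound
#' criteria are excluded as structured fields.
#'
#' @inheritParams detect_temporal
#' @return `list(flag, evidence)` as in [detect_temporal()].
#' @export
detect_lab_or_score <- function(text, rules = load_rule_pack()) {
  norm <- normalize_criterion_text(text)
  if (age_excluded(norm, rules)) return(list(flag = FALSE, evidence = empty_evidence()))
  term <- match_span(norm, rules$lab$term_re)
  num <- match_span(norm, rules$lab$numeric_re)
  if (is.null(term) || is.null(num)) return(list(flag = FALSE, evidence = empty_evidence()))
  list(flag = TRUE,
       evidence = rbind(evidence_row("lab_or_score", text, term),
                        evidence_row("lab_or_score", text, num)))
}

#' Detect patient-dependent criteria (behavior or abilities)
#'
#' Fires on volition/ability phrases (willing to, able to, must agree,
#' capable of, compliance with, consent to, ...) — criteria that no
#' record system can evaluate without asking the patient.
#'
#' @inheritParams detect_temporal
#' @return `list(flag, evidence)` as in [detect_temporal()].
#' @export
detect_patient_dependency <- function(text, rules = load_rule_pack()) {
  norm <- normalize_criterion_text(text)
  span <- match_span(norm, rules$patient$phrases_re)
  if (is.null(span)) return(list(flag = FALSE, evidence = empty_evidence()))
  list(flag = TRUE, evidence = evidence_row("patient_dependent", text, span))
}

#' Detect sub-population scoping across a trial's criteria
#'
#' A criterion scopes a sub-population either lexically (a conditional
#' marker: if, unless, only applies, for patients with, ...) or
#' structurally: a criterion indented beneath a parent whose text names a
#' condition subgroup ("Patients with hepatic involvement:") applies only
#' to that subgroup. The structural rule attributes the flag (and the
#' evidence) to the parent criterion.
#'
#' @param criteria `data.frame` from [segment_criteria()] (needs `text`
#'   and `indent_depth`).
#' @param rules A [load_rule_pack()] result.
#' @return `list(flag, criterion_flags, evidence)`; `criterion_flags` is
#'   a logical vector aligned with `criteria` rows, `evidence` carries a
#'   `criterion` row-index column.
#' @export
detect_subpopulation <- function(criteria, rules = load_rule_pack()) {
  n <- nrow(criteria)
  flags <- logical(n)
  ev <- list()
  for (i in seq_len(n)) {
    norm <- normalize_criterion_text(criteria$text[i])
    span <- match_span(norm, rules$subpopulation$markers_re)
    if (!is.null(span)) {
      flags[i] <- TRUE
      row <- evidence_row("subpopulation", criteria$text[i], span)
      row$criterion <- i
      ev[[length(ev) + 1L]] <- row
    }
    # structural rule: indented child under a subgroup-naming parent
    if (criteria$indent_depth[i] >= 1L) {
      parents <- which(criteria$indent_depth[seq_len(i - 1L)] < criteria$indent_depth[i])
      if (length(parents)) {
        p <- max(parents)
        pnorm <- normalize_criterion_text(criteria$text[p])
        if (grepl(rules$subpopulation$header_re, pnorm, perl = TRUE) && !flags[p]) {
          flags[p] <- TRUE
          row <- evidence_row("subpopulation", criteria$text[p],
                              c(start = 1L, end = nchar(criteria$text[p])))
          row$criterion <- p
          ev[[length(ev) + 1L]] <- row
        }
      }
    }
  }
  list(flag = any(flags), criterion_flags = flags,
       evidence = if (length(ev)) do.call(rbind, ev) else
         cbind(empty_evidence(), criterion = integer(0)))
}

#' Per-criterion barrier flags for one trial
#'
#' Runs all four detectors over a trial's segmented criteria. A
#' criterion can carry several category flags at once (e.g. a temporally
#' constrained lab value); there is no mutual exclusion.
#'
#' @inheritParams detect_subpopulation
#' @return `list(criteria = data.frame with logical columns
#'   subpopulation, lab_or_score, temporal, patient_dependent appended,
#'   evidence = data.frame of spans with criterion indices)`.
#' @export
annotate_criteria <- function(criteria, rules = load_rule_pack()) {
  n <- nrow(criteria)
  sub <- detect_subpopulation(criteria, rules)
  temporal <- logical(n); lab <- logical(n); pat <- logical(n)
  ev <- list(sub$evidence)
  for (i in seq_len(n)) {
    for (det in list(list(f = detect_temporal, col = "temporal"),
                     list(f = detect_lab_or_score, col = "lab"),
                     list(f = detect_patient_dependency, col = "pat"))) {
      res <- det$f(criteria$text[i], rules)
      if (res$flag) {
        if (det$col == "temporal") temporal[i] <- TRUE
        else if (det$col == "lab") lab[i] <- TRUE
        else pat[i] <- TRUE
        res$evidence$criterion <- i
        ev[[length(ev) + 1L]] <- res$evidence
      }
    }
  }
  out <- criteria
  out$subpopulation <- sub$criterion_flags
  out$lab_or_score <- lab
  out$temporal <- temporal
  out$patient_dependent <- pat
  list(criteria = out, evidence = do.call(rbind, ev))
}

# fallback segmentation for trials matching neither macro-format:
# every nonblank line becomes a pseudo-criterion at depth 0
degraded_criteria <- function(eligibility_text) {
  lines <- trimws(split_lines(eligibility_text))
  lines <- lines[nzchar(lines)]
  data.frame(ordinal = seq_along(lines), role = "inclusion",
             indent_depth = 0L, negated = FALSE, text = lines,
             stringsAsFactors = FALSE)
}

#' Trial-level barrier flags
#'
#' Aggregates per-criterion detector output to one row per trial: each
#' category flag is the OR over the trial's criteria, `any` is the OR of
#' the four categories, and counts give the number of flagged criteria
#' per category. Unsegmentable trials are annotated from their raw lines
#' and marked `degraded`.
#'
#' @param criteria Segmented criteria of one trial ([segment_criteria()]),
#'   or `NULL` together with `eligibility_text` for degraded mode.
#' @param rules A [load_rule_pack()] result.
#' @param nct_id Trial identifier for the output row.
#' @param eligibility_text Raw textblock, used only when `criteria` is
#'   `NULL`.
#' @return One-row `data.frame`: flags, `any`, per-category counts,
#'   `degraded`, `rules_version`.
#' @export
annotate_trial <- function(criteria, rules = load_rule_pack(),
                           nct_id = NA_character_, eligibility_text = NULL) {
  degraded <- is.null(criteria)
  if (degraded) criteria <- degraded_criteria(eligibility_text %||% "")
  ann <- annotate_criteria(criteria, rules)$criteria
  data.frame(
    nct_id = nct_id,
    subpopulation = any(ann$subpopulation),
    lab_or_score = any(ann$lab_or_score),
    temporal = any(ann$temporal),
    patient_dependent = any(ann$patient_dependent),
    any = any(ann$subpopulation, ann$lab_or_score, ann$temporal,
              ann$patient_dependent),
    n_subpopulation = sum(ann$subpopulation),
    n_lab_or_score = sum(ann$lab_or_score),
    n_temporal = sum(ann$temporal),
    n_patient_dependent = sum(ann$patient_dependent),
    degraded = degraded,
    rules_version = rules$version,
    stringsAsFactors = FALSE)
}

#' Annotate every trial in a corpus
#'
#' @param corpus A [ctg_corpus()].
#' @param rules A [load_rule_pack()] result.
#' @return A list: `trials` (one [annotate_trial()] row per record, plus
#'   `domain_tag`), `criteria` (all per-criterion flags with `nct_id`).
#' @export
annotate_corpus <- function(corpus, rules = load_rule_pack()) {
  seg <- segment_corpus(corpus)
  crit_by_id <- if (!is.null(seg$criteria)) split(seg$criteria, seg$criteria$nct_id) else list()
  trial_rows <- list(); crit_rows <- list()
  for (r in corpus$records) {
    crit <- crit_by_id[[r$nct_id]]
    if (r$nct_id %in% seg$unsegmentable) crit <- NULL
    row <- annotate_trial(crit, rules, nct_id = r$nct_id,
                          eligibility_text = r$eligibility_text)
    row$domain_tag <- r$domain_tag
    trial_rows[[length(trial_rows) + 1L]] <- row
    used <- if (is.null(crit)) degraded_criteria(r$eligibility_text) else crit
    ann <- annotate_criteria(used, rules)$criteria
    ann$nct_id <- r$nct_id
    ann$domain_tag <- r$domain_tag
    crit_rows[[length(crit_rows) + 1L]] <- ann
  }
  crit <- do.call(rbind, crit_rows)
  rownames(crit) <- NULL
  list(trials = do.call(rbind, trial_rows), criteria = crit)
}

#' Per-domain barrier prevalence table
#'
#' Whole-percent share of trials flagged per category plus the `any`
#' column (at least one of the four barriers), per domain and overall.
#'
#' @param x A [ctg_corpus()] or the `trials` data frame from
#'   [annotate_corpus()].
#' @param rules A [load_rule_pack()] result (used only when `x` is a
#'   corpus).
#' @return `data.frame` with columns `domain_tag`, `n_trials` and the
#'   five percent columns.
#' @export
barrier_table <- function(x, rules = load_rule_pack()) {
  trials <- if (inherits(x, "ctg_corpus")) annotate_corpus(x, rules)$trials else x
  cats <- c("subpopulation", "lab_or_score", "temporal", "patient_dependent", "any")
  doms <- sort(unique(trials$domain_tag))
  rows <- lapply(c(doms, "overall"), function(d) {
    sub <- if (d == "overall") trials else trials[trials$domain_tag == d, ]
    cbind(data.frame(domain_tag = d, n_trials = nrow(sub), stringsAsFactors = FALSE),
          as.data.frame(setNames(
            lapply(cats, function(cc) percent_of(sum(sub[[cc]]), nrow(sub))),
            paste0("percent_", cats))))
  })
  do.call(rbind, rows)
}
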