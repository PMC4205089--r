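# line-level helpers shared by classification and segmentation

split_lines <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  gsub("\t", "    ", lines, fixed = TRUE)
}

.bullet_re <- "^( *)(-|\\*|•|[0-9]+\\.) +"

is_bullet <- function(lines) grepl(.bullet_re, lines)

line_indent <- function(line) nchar(sub("^( *).*$", "\\1", line))

# heading matchers tolerate trailing colons, leading numbering, any case
.incl_re <- "inclusion criteria"
.excl_re <- "exclusion criteria"
.topic_res <- c(disease = "disease characteristics",
                patient = "patient characteristics",
                prior = "prior (and )?concurrent therapy")

first_match <- function(lines, re) {
  hits <- grep(re, lines, ignore.case = TRUE)
  if (length(hits)) hits[1] else NA_integer_
}

#' Classify an eligibility textblock's macro-format
#'
#' Two machine-recognizable layouts exist for registry eligibility text:
#' the *suggested* format (a bulleted list under "Inclusion Criteria"
#' then, optionally, "Exclusion Criteria", in that order) and the
#' *extended* format common in cancer trials (inclusion-only, possibly
#' negated items under the topics "disease characteristics", "patient
#' characteristics" and "prior concurrent therapy"). A text matching at
#' least two of the three topic headings, each followed by a bulleted
#' list, counts as extended. Unclassifiable text yields all-`FALSE`,
#' never an error.
#'
#' @param eligibility_text The (dedented) textblock.
#' @return A list with logicals `suggested`, `extended`,
#'   `either` (`= suggested | extended`).
#' @export
classify_format <- function(eligibility_text) {
  lines <- split_lines(eligibility_text)
  if (length(lines) == 0L)
    return(list(suggested = FALSE, extended = FALSE, either = FALSE))
  bullets <- is_bullet(lines)

  incl <- first_match(lines, .incl_re)
  excl <- first_match(lines, .excl_re)
  suggested <- !is.na(incl) &&
    (is.na(excl) || incl < excl) &&
    any(bullets & seq_along(lines) > incl)

  topic_idx <- vapply(.topic_res, function(re) first_match(lines, re), integer(1))
  present <- !is.na(topic_idx)
  if (sum(present) >= 2) {
    all_heads <- sort(c(topic_idx[present], incl, excl))
    all_heads <- all_heads[!is.na(all_heads)]
    listed <- vapply(topic_idx[present], function(i) {
      nxt <- all_heads[all_heads > i]
      end <- if (length(nxt)) nxt[1] - 1L else length(lines)
      i < end && any(bullets[(i + 1L):end])
    }, logical(1))
    extended <- sum(listed) >= 2
  } else extended <- FALSE

  list(suggested = suggested, extended = extended,
       either = suggested || extended)
}

# section table for segmentation: start/end line, role, extended mode
format_sections <- function(lines, classification) {
  incl <- first_match(lines, .incl_re)
  excl <- first_match(lines, .excl_re)
  if (classification$suggested) {
    secs <- list(list(start = incl + 1L,
                      end = if (!is.na(excl) && excl > incl) excl - 1L else length(lines),
                      role = "inclusion", extended = FALSE))
    if (!is.na(excl) && excl > incl && excl < length(lines))
      secs <- c(secs, list(list(start = excl + 1L, end = length(lines),
                                role = "exclusion", extended = FALSE)))
    return(secs)
  }
  topic_idx <- vapply(.topic_res, function(re) first_match(lines, re), integer(1))
  topic_idx <- sort(topic_idx[!is.na(topic_idx)])
  lapply(seq_along(topic_idx), function(k) {
    list(start = topic_idx[k] + 1L,
         end = if (k < length(topic_idx)) topic_idx[k + 1L] - 1L else length(lines),
         role = "inclusion", extended = TRUE)
  })
}

#' Segment an eligibility textblock into individual criteria
#'
#' One criterion per bullet. Recognized bullet markers: leading `-`, `*`,
#' `•` or `N.` (digit + dot). Continuation lines (no marker, at
#' least the bullet's indent) are joined with a single space. The role
#' (inclusion/exclusion) comes from the governing heading; all
#' extended-format items are inclusion criteria, with items beginning
#' "No ..." flagged as negated. Indent depth is measured relative to the
#' section's first bullet, one depth unit per additional step of at least
#' two spaces (tabs expand to 4 spaces).
#'
#' @param eligibility_text The (dedented) textblock.
#' @param classification Optional result of [classify_format()]; computed
#'   when omitted. Segmentation refuses texts with `either = FALSE`.
#' @return `data.frame`: `ordinal` (within role), `role`, `indent_depth`,
#'   `negated`, `text`.
#' @export
segment_criteria <- function(eligibility_text, classification = NULL) {
  if (is.null(classification)) classification <- classify_format(eligibility_text)
  if (!isTRUE(classification$either))
    stop_ctg("text matches neither eligibility format; cannot segment",
             "ctg_format_error")
  lines <- split_lines(eligibility_text)
  secs <- format_sections(lines, classification)

  out <- list()
  counters <- c(inclusion = 0L, exclusion = 0L)
  for (sec in secs) {
    if (sec$start > sec$end) next
    stack <- integer(0)  # indent stack; depth = position - 1
    cur <- NULL
    flush <- function() {
      if (is.null(cur)) return()
      counters[[cur$role]] <<- counters[[cur$role]] + 1L
      cur$ordinal <- counters[[cur$role]]
      out[[length(out) + 1L]] <<- cur
    }
    for (i in sec$start:sec$end) {
      line <- lines[i]
      if (!nzchar(trimws(line))) next
      if (grepl(.bullet_re, line)) {
        flush()
        indent <- line_indent(line)
        text <- trimws(sub(.bullet_re, "", line))
        if (length(stack) == 0L) {
          stack <- indent
        } else {
          while (length(stack) > 1L && indent < stack[length(stack)])
            stack <- stack[-length(stack)]
          if (indent < stack[1L]) stack[1L] <- indent
          else if (indent >= stack[length(stack)] + 2L)
            stack <- c(stack, indent)
        }
        cur <- list(text = text, role = sec$role,
                    indent_depth = length(stack) - 1L,
                    negated = sec$extended && grepl("^no\\b", tolower(text)),
                    bullet_indent = indent)
      } else if (!is.null(cur) && line_indent(line) >= cur$bullet_indent) {
        cur$text <- paste(cur$text, trimws(line))
      }
      # stray lines (non-bullet, shallower indent) are ignored
    }
    flush()
  }
  if (length(out) == 0L)
    return(data.frame(ordinal = integer(0), role = character(0),
                      indent_depth = integer(0), negated = logical(0),
                      text = character(0), stringsAsFactors = FALSE))
  data.frame(
    ordinal = vapply(out, `[[`, integer(1), "ordinal"),
    role = vapply(out, `[[`, character(1), "role"),
    indent_depth = vapply(out, `[[`, integer(1), "indent_depth"),
    negated = vapply(out, `[[`, logical(1), "negated"),
    text = vapply(out, `[[`, character(1), "text"),
    stringsAsFactors = FALSE)
}

#' Classify and segment every record in a corpus
#'
#' @param corpus A [ctg_corpus()].
#' @return A list: `classifications` (`data.frame` per trial with
#'   `suggested`/`extended`/`either`), `criteria` (`data.frame` of all
#'   segmented criteria with `nct_id` and `domain_tag` columns), and
#'   `unsegmentable` (ids of trials matching neither format, excluded
#'   from criterion counts and reported separately).
#' @export
segment_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "ctg_corpus"))
  cls_rows <- list(); crit_rows <- list(); bad <- character(0)
  for (r in corpus$records) {
    cls <- classify_format(r$eligibility_text)
    cls_rows[[length(cls_rows) + 1L]] <- data.frame(
      nct_id = r$nct_id, domain_tag = r$domain_tag,
      suggested = cls$suggested, extended = cls$extended, either = cls$either,
      stringsAsFactors = FALSE)
    if (cls$either) {
      crit <- segment_criteria(r$eligibility_text, cls)
      if (nrow(crit)) {
        crit$nct_id <- r$nct_id
        crit$domain_tag <- r$domain_tag
        crit_rows[[length(crit_rows) + 1L]] <- crit
      }
    } else bad <- c(bad, r$nct_id)
  }
  list(classifications = do.call(rbind, cls_rows),
       criteria = if (length(crit_rows)) do.call(rbind, crit_rows) else NULL,
       unsegmentable = bad)
}

#' Per-domain eligibility-format table
#'
#' Whole-percent shares of trials in the suggested format and in either
#' machine-recognizable format, per domain plus an overall row (overall
#' computed from trial totals, i.e. weighted by domain size).
#'
#' @param x A [ctg_corpus()] or the `classifications` data frame from
#'   [segment_corpus()].
#' @return `data.frame`: `domain_tag`, `n_trials`, `percent_suggested`,
#'   `percent_either`.
#' @export
format_table <- function(x) {
  cls <- if (inherits(x, "ctg_corpus")) segment_corpus(x)$classifications else x
  doms <- sort(unique(cls$domain_tag))
  rows <- lapply(doms, function(d) {
    sub <- cls[cls$domain_tag == d, ]
    data.frame(domain_tag = d, n_trials = nrow(sub),
               n_suggested = sum(sub$suggested), n_either = sum(sub$either),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(domain_tag = "overall",
                               n_trials = sum(tab$n_trials),
                               n_suggested = sum(tab$n_suggested),
                               n_either = sum(tab$n_either)))
  tab$percent_suggested <- percent_of(tab$n_suggested, tab$n_trials)
  tab$percent_either <- percent_of(tab$n_either, tab$n_trials)
  tab
}
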