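#' @importFrom stats setNames rnbinom rgamma rpois runif
#' @importFrom utils read.csv write.csv head
NULL

# canonical recruitment-status vocabulary: XML string <-> internal code.
.status_map <- c(
  "Not yet recruiting"      = "not_yet_recruiting",
  "Recruiting"              = "recruiting",
  "Active, not recruiting"  = "active_not_recruiting",
  "Completed"               = "completed",
  "Terminated"              = "terminated",
  "Withdrawn"               = "withdrawn",
  "Suspended"               = "suspended",
  "Enrolling by invitation" = "enrolling_by_invitation",
  "Unknown status"          = "unknown"
)

#' Recruitment statuses counted as "open"
#'
#' The audit treats exactly "Recruiting" and "Not yet recruiting" as open
#' for recruitment; every other status (including unrecognized strings,
#' which map to `unknown`) is not open.
#'
#' @return Character vector of internal status codes.
#' @export
open_statuses <- function() c("not_yet_recruiting", "recruiting")

parse_status <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return("unknown")
  hit <- match(tolower(trimws(text)), tolower(names(.status_map)))
  if (is.na(hit)) "unknown" else unname(.status_map[hit])
}

format_status <- function(code) {
  hit <- match(code, .status_map)
  if (is.na(hit)) "Unknown status" else names(.status_map)[hit]
}

#' Contact details for a trial or location
#'
#' @param name Contact name (free text).
#' @param phone,email Optional strings; at least one must be present —
#'   a contact with neither is not representable and should be omitted
#'   from the record instead.
#' @return An object of class `contact_info`.
#' @export
contact_info <- function(name, phone = NULL, email = NULL) {
  phone <- if (is.null(phone) || is.na(phone) || !nzchar(phone)) NULL else as.character(phone)
  email <- if (is.null(email) || is.na(email) || !nzchar(email)) NULL else as.character(email)
  if (is.null(phone) && is.null(email))
    stop_ctg("a contact needs at least one of phone/email", "ctg_record_error")
  structure(list(name = as.character(name), phone = phone, email = email),
            class = "contact_info")
}

#' A recruitment location on a trial record
#'
#' @param facility,city,country Free-text place fields.
#' @param latitude,longitude Optional decimal degrees (city-level
#'   accuracy); validated against the usual ranges.
#' @param contact Optional [contact_info()].
#' @return An object of class `trial_location`.
#' @export
trial_location <- function(facility, city, country,
                           latitude = NULL, longitude = NULL, contact = NULL) {
  if (!is.null(latitude)) {
    latitude <- as.numeric(latitude)
    if (is.na(latitude) || latitude < -90 || latitude > 90)
      stop_ctg("latitude out of [-90, 90]", "ctg_coord_error")
  }
  if (!is.null(longitude)) {
    longitude <- as.numeric(longitude)
    if (is.na(longitude) || longitude < -180 || longitude > 180)
      stop_ctg("longitude out of [-180, 180]", "ctg_coord_error")
  }
  if (!is.null(contact)) stopifnot(inherits(contact, "contact_info"))
  structure(list(facility = as.character(facility), city = as.character(city),
                 country = as.character(country),
                 latitude = latitude, longitude = longitude, contact = contact),
            class = "trial_location")
}

#' A single registry trial record
#'
#' In-memory model of one `clinical_study` document: identifiers, overall
#' recruitment status, fuzzy dates, the raw eligibility textblock,
#' locations and contact details, plus the corpus domain tag.
#'
#' @param nct_id Registry identifier, `NCT` followed by 8 digits.
#' @param domain_tag Corpus label (e.g. `"gleevec"`); carried on the
#'   manifest but modeled on the record.
#' @param overall_status Internal status code (see [open_statuses()]).
#' @param first_received,last_update [fuzzy_date()]s; `last_update` must
#'   not precede `first_received` when both have day precision.
#' @param completion_date Optional [fuzzy_date()] ("the final date on
#'   which data was or is expected to be collected").
#' @param eligibility_text Raw eligibility textblock (multi-line).
#' @param minimum_age,maximum_age Optional free-text age bounds
#'   (structured registry fields, e.g. `"18 Years"`).
#' @param gender One of `"all"`, `"female"`, `"male"`.
#' @param healthy_volunteers Logical flag.
#' @param locations List of [trial_location()]s (ordered).
#' @param overall_contact,backup_contact Optional [contact_info()]s.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(nct_id, domain_tag = NA_character_,
                         overall_status = "unknown",
                         first_received, last_update,
                         completion_date = NULL,
                         eligibility_text = "",
                         minimum_age = NULL, maximum_age = NULL,
                         gender = "all", healthy_volunteers = FALSE,
                         locations = list(),
                         overall_contact = NULL, backup_contact = NULL) {
  if (!grepl("^NCT[0-9]{8}$", nct_id))
    stop_ctg(sprintf("invalid nct_id '%s'", nct_id), "ctg_id_error")
  stopifnot(inherits(first_received, "fuzzy_date"),
            inherits(last_update, "fuzzy_date"))
  if (first_received$precision == "day" && last_update$precision == "day" &&
      latest_day(last_update) < latest_day(first_received))
    stop_ctg("last_update precedes first_received", "ctg_record_error")
  if (!is.null(completion_date)) stopifnot(inherits(completion_date, "fuzzy_date"))
  gender <- match.arg(gender, c("all", "female", "male"))
  overall_status <- match.arg(overall_status, unname(c(.status_map)))
  stopifnot(is.list(locations))
  for (loc in locations) stopifnot(inherits(loc, "trial_location"))
  if (!is.null(overall_contact)) stopifnot(inherits(overall_contact, "contact_info"))
  if (!is.null(backup_contact)) stopifnot(inherits(backup_contact, "contact_info"))
  structure(list(
    nct_id = nct_id, domain_tag = as.character(domain_tag),
    overall_status = overall_status,
    first_received = first_received, last_update = last_update,
    completion_date = completion_date,
    eligibility_text = as.character(eligibility_text),
    minimum_age = if (is.null(minimum_age)) NULL else as.character(minimum_age),
    maximum_age = if (is.null(maximum_age)) NULL else as.character(maximum_age),
    gender = gender, healthy_volunteers = isTRUE(healthy_volunteers),
    locations = locations,
    overall_contact = overall_contact, backup_contact = backup_contact),
    class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s [%s] %s, %d location(s), updated %s>\n",
              x$nct_id, x$domain_tag, x$overall_status,
              length(x$locations), format(x$last_update)))
  invisible(x)
}

#' A corpus of trial records with per-domain reference dates
#'
#' The reference date plays the role of "today" for the audit: it is the
#' date the records were retrieved, carried on the manifest rather than
#' taken from the wall clock, so audits are reproducible.
#'
#' @param records List of [trial_record()]s; `nct_id`s must be unique.
#' @param reference_dates Named `Date` vector (names = domain tags), or a
#'   single unnamed `Date` applied to every domain.
#' @param provenance Free-text description of where the corpus came from.
#' @return An object of class `ctg_corpus`.
#' @export
ctg_corpus <- function(records, reference_dates, provenance = "") {
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$nct_id, character(1))
  if (anyDuplicated(ids))
    stop_ctg("duplicate nct_id in corpus", "ctg_id_error")
  reference_dates <- as.Date(reference_dates)
  structure(list(records = records, reference_dates = reference_dates,
                 provenance = provenance),
            class = "ctg_corpus")
}

#' @export
print.ctg_corpus <- function(x, ...) {
  doms <- table(vapply(x$records, function(r) r$domain_tag, character(1)))
  cat(sprintf("<ctg_corpus: %d records over %d domain(s)>\n",
              length(x$records), length(doms)))
  for (d in names(doms)) cat(sprintf("  %s: %d\n", d, doms[[d]]))
  invisible(x)
}

#' Reference date for a domain
#'
#' @param corpus A [ctg_corpus()].
#' @param domain_tag Domain label.
#' @return A `Date`.
#' @export
reference_date_for <- function(corpus, domain_tag) {
  rd <- corpus$reference_dates
  if (is.null(names(rd)) || length(rd) == 1L && !nzchar(names(rd)[1] %||% ""))
    return(rd[[1]])
  if (!domain_tag %in% names(rd))
    stop_ctg(sprintf("no reference date for domain '%s'", domain_tag),
             "ctg_record_error")
  rd[[domain_tag]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- XML dialect -----------------------------------------------------

xml_text_or_null <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) return(NULL)
  txt <- xml2::xml_text(node)
  if (!nzchar(trimws(txt))) NULL else trimws(txt)
}

read_contact_node <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) return(NULL)
  name <- xml_text_or_null(node, "./last_name") %||% ""
  phone <- xml_text_or_null(node, "./phone")
  email <- xml_text_or_null(node, "./email")
  if (is.null(phone) && is.null(email)) return(NULL)
  contact_info(name, phone, email)
}

#' Read one trial record from classic registry XML
#'
#' Parses a `clinical_study` document. Unknown status strings map to
#' `"unknown"` (never an error, so audits degrade gracefully); missing
#' optional elements map to absent fields; the eligibility textblock has
#' its common leading indent stripped while relative indentation — which
#' is semantic for sub-population detection — is preserved.
#'
#' @param x Path to an XML file, or a single XML string.
#' @param domain_tag Domain label to attach when the document does not
#'   carry one itself.
#' @return A [trial_record()].
#' @export
read_trial_xml <- function(x, domain_tag = NA_character_) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) stop_ctg(
                    paste0("malformed XML: ", conditionMessage(e)),
                    "ctg_parse_error"))
  if (xml2::xml_name(doc) != "clinical_study")
    stop_ctg("root element is not <clinical_study>", "ctg_parse_error")
  nct <- xml_text_or_null(doc, ".//id_info/nct_id")
  if (is.null(nct))
    stop_ctg("record rejected: missing nct_id", "ctg_id_error")
  dom <- xml2::xml_attr(doc, "domain")
  if (is.na(dom)) dom <- domain_tag

  fr <- xml_text_or_null(doc, "./study_first_submitted")
  lu <- xml_text_or_null(doc, "./last_update_submitted")
  if (is.null(fr) || is.null(lu))
    stop_ctg(sprintf("%s: missing first/last submitted dates", nct),
             "ctg_parse_error")
  cd <- xml_text_or_null(doc, "./completion_date")

  elig <- xml2::xml_find_first(doc, "./eligibility/criteria/textblock")
  elig_text <- if (inherits(elig, "xml_missing")) "" else
    strip_common_indent(xml2::xml_text(elig))

  hv <- xml_text_or_null(doc, "./eligibility/healthy_volunteers")
  gender <- tolower(xml_text_or_null(doc, "./eligibility/gender") %||% "all")
  if (!gender %in% c("all", "female", "male")) gender <- "all"

  min_age <- xml_text_or_null(doc, "./eligibility/minimum_age")
  max_age <- xml_text_or_null(doc, "./eligibility/maximum_age")
  if (identical(min_age, "N/A")) min_age <- NULL
  if (identical(max_age, "N/A")) max_age <- NULL

  locs <- lapply(xml2::xml_find_all(doc, "./location"), function(node) {
    lat <- xml_text_or_null(node, "./latitude")
    lon <- xml_text_or_null(node, "./longitude")
    trial_location(
      facility = xml_text_or_null(node, "./facility/name") %||% "",
      city = xml_text_or_null(node, "./facility/address/city") %||% "",
      country = xml_text_or_null(node, "./facility/address/country") %||% "",
      latitude = if (is.null(lat)) NULL else as.numeric(lat),
      longitude = if (is.null(lon)) NULL else as.numeric(lon),
      contact = read_contact_node(node, "./contact"))
  })

  trial_record(
    nct_id = nct, domain_tag = dom,
    overall_status = parse_status(xml_text_or_null(doc, "./overall_status")),
    first_received = parse_fuzzy_date(fr),
    last_update = parse_fuzzy_date(lu),
    completion_date = if (is.null(cd)) NULL else parse_fuzzy_date(cd),
    eligibility_text = elig_text,
    minimum_age = min_age, maximum_age = max_age,
    gender = gender,
    healthy_volunteers = identical(tolower(hv %||% "no"), "accepts healthy volunteers") ||
      identical(tolower(hv %||% "no"), "yes"),
    locations = locs,
    overall_contact = read_contact_node(doc, "./overall_contact"),
    backup_contact = read_contact_node(doc, "./overall_contact_backup"))
}

contact_xml <- function(tag, contact) {
  if (is.null(contact)) return(character(0))
  c(sprintf("  <%s>", tag),
    sprintf("    <last_name>%s</last_name>", xml_escape(contact$name)),
    if (!is.null(contact$phone)) sprintf("    <phone>%s</phone>", xml_escape(contact$phone)),
    if (!is.null(contact$email)) sprintf("    <email>%s</email>", xml_escape(contact$email)),
    sprintf("  </%s>", tag))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Serialize a trial record to the classic registry XML dialect
#'
#' Emits the same dialect [read_trial_xml()] consumes; reading back a
#' written record reproduces it on every modeled field. Month-precision
#' dates serialize as `"Month YYYY"`, the textblock is indented in the
#' registry's 8-space style.
#'
#' @param record A [trial_record()].
#' @return A single XML string.
#' @export
write_trial_xml <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  dom_attr <- if (is.na(record$domain_tag)) "" else
    sprintf(' domain="%s"', xml_escape(record$domain_tag))
  elig_lines <- strsplit(record$eligibility_text, "\n", fixed = TRUE)[[1]]
  if (length(elig_lines) == 0L) elig_lines <- ""
  indented <- ifelse(nzchar(elig_lines), paste0("        ", elig_lines), "")
  loc_xml <- unlist(lapply(record$locations, function(loc) {
    c("  <location>",
      "    <facility>",
      sprintf("      <name>%s</name>", xml_escape(loc$facility)),
      "      <address>",
      sprintf("        <city>%s</city>", xml_escape(loc$city)),
      sprintf("        <country>%s</country>", xml_escape(loc$country)),
      "      </address>",
      "    </facility>",
      if (!is.null(loc$latitude)) sprintf("    <latitude>%.6f</latitude>", loc$latitude),
      if (!is.null(loc$longitude)) sprintf("    <longitude>%.6f</longitude>", loc$longitude),
      if (!is.null(loc$contact)) paste0("  ", contact_xml("contact", loc$contact)),
      "  </location>")
  }))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf("<clinical_study%s>", dom_attr),
    "  <id_info>",
    sprintf("    <nct_id>%s</nct_id>", record$nct_id),
    "  </id_info>",
    sprintf("  <overall_status>%s</overall_status>",
            xml_escape(format_status(record$overall_status))),
    sprintf("  <study_first_submitted>%s</study_first_submitted>",
            format(record$first_received)),
    sprintf("  <last_update_submitted>%s</last_update_submitted>",
            format(record$last_update)),
    if (!is.null(record$completion_date))
      sprintf("  <completion_date>%s</completion_date>",
              format(record$completion_date)),
    "  <eligibility>",
    "    <criteria>",
    "      <textblock>",
    indented,
    "      </textblock>",
    "    </criteria>",
    sprintf("    <gender>%s</gender>",
            c(all = "All", female = "Female", male = "Male")[[record$gender]]),
    sprintf("    <minimum_age>%s</minimum_age>", xml_escape(record$minimum_age %||% "N/A")),
    sprintf("    <maximum_age>%s</maximum_age>", xml_escape(record$maximum_age %||% "N/A")),
    sprintf("    <healthy_volunteers>%s</healthy_volunteers>",
            if (record$healthy_volunteers) "Accepts Healthy Volunteers" else "No"),
    "  </eligibility>",
    loc_xml,
    contact_xml("overall_contact", record$overall_contact),
    contact_xml("overall_contact_backup", record$backup_contact),
    "</clinical_study>")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Strip the common leading indent of a textblock
#'
#' Registry textblocks arrive uniformly indented; the common indent of the
#' non-blank lines is removed (tabs expanded to 4 spaces first) and
#' leading/trailing blank lines dropped. Relative indentation survives.
#'
#' @param text Multi-line string.
#' @return The dedented string.
#' @export
strip_common_indent <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- gsub("\t", "    ", lines, fixed = TRUE)
  nonblank <- nzchar(trimws(lines))
  if (!any(nonblank)) return("")
  # drop leading/trailing blank lines
  rng <- range(which(nonblank))
  lines <- lines[rng[1]:rng[2]]
  nonblank <- nzchar(trimws(lines))
  indents <- nchar(sub("^( *).*$", "\\1", lines[nonblank]))
  common <- min(indents)
  lines[nzchar(trimws(lines))] <- substring(lines[nzchar(trimws(lines))], common + 1L)
  lines[!nzchar(trimws(lines))] <- ""
  paste(lines, collapse = "\n")
}

## ---- corpus directory / manifest -------------------------------------

#' Write a corpus as one XML file per trial plus a manifest
#'
#' The manifest (`manifest.csv`) carries `nct_id`, `domain_tag`, `file`
#' and the per-domain `reference_date` (ISO-8601), the corpus's notion of
#' "today".
#'
#' @param corpus A [ctg_corpus()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "ctg_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(corpus$records, function(r) {
    file <- paste0(r$nct_id, ".xml")
    writeLines(write_trial_xml(r), file.path(dir, file), useBytes = TRUE)
    data.frame(nct_id = r$nct_id, domain_tag = r$domain_tag, file = file,
               reference_date = as.character(reference_date_for(corpus, r$domain_tag)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a corpus from a manifest
#'
#' @param manifest Path to a `manifest.csv` written by [write_corpus()]
#'   (or a directory containing one).
#' @return A [ctg_corpus()].
#' @export
read_corpus <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  records <- Map(function(file, dom) read_trial_xml(file.path(base, file), dom),
                 man$file, man$domain_tag)
  names(records) <- NULL
  refs <- tapply(as.Date(man$reference_date), man$domain_tag, max)
  ctg_corpus(records, as.Date(refs, origin = "1970-01-01"),
             provenance = paste("read from", manifest))
}

#' Flat tabular export of scalar record fields
#'
#' One row per trial with every scalar field; list-valued fields are
#' summarized (`n_locations`, presence flags for contacts).
#'
#' @param corpus A [ctg_corpus()].
#' @return A `data.frame`.
#' @export
corpus_table <- function(corpus) {
  rows <- lapply(corpus$records, function(r) {
    data.frame(
      nct_id = r$nct_id, domain_tag = r$domain_tag,
      overall_status = r$overall_status,
      first_received = format(r$first_received),
      last_update = format(r$last_update),
      completion_date = if (is.null(r$completion_date)) NA_character_ else
        format(r$completion_date),
      minimum_age = r$minimum_age %||% NA_character_,
      maximum_age = r$maximum_age %||% NA_character_,
      gender = r$gender, healthy_volunteers = r$healthy_volunteers,
      n_locations = length(r$locations),
      has_overall_contact = !is.null(r$overall_contact),
      has_backup_contact = !is.null(r$backup_contact),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
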