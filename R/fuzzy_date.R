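#' Partially specified registry dates
#'
#' ClinicalTrials.gov exposes several dates ("study completion date",
#' "date last updated", ...) at year, month or day precision. A
#' `fuzzy_date` carries the stated components plus an explicit precision
#' so that downstream comparisons can choose an interpretation instead of
#' silently coercing.
#'
#' @param year Integer year.
#' @param month Optional integer month (1-12); required for `"month"` and
#'   `"day"` precision, forbidden for `"year"`.
#' @param day Optional integer day of month; required for `"day"`
#'   precision, forbidden otherwise.
#' @param precision One of `"year"`, `"month"`, `"day"`. Inferred from the
#'   supplied components when omitted.
#' @return An object of class `fuzzy_date`.
#' @examples
#' fuzzy_date(2013, 6, 6)
#' fuzzy_date(2012, 6)          # month precision
#' latest_day(fuzzy_date(2012, 2))  # leap year -> "2012-02-29"
#' @export
fuzzy_date <- function(year, month = NULL, day = NULL, precision = NULL) {
  year <- as.integer(year)
  month <- if (is.null(month) || is.na(month)) NA_integer_ else as.integer(month)
  day <- if (is.null(day) || is.na(day)) NA_integer_ else as.integer(day)
  if (is.null(precision)) {
    precision <- if (!is.na(day)) "day" else if (!is.na(month)) "month" else "year"
  }
  precision <- match.arg(precision, c("year", "month", "day"))
  if (is.na(year)) stop_ctg("fuzzy_date requires a year", "ctg_date_error")
  if (precision == "day") {
    if (is.na(month) || is.na(day))
      stop_ctg("day precision requires month and day", "ctg_date_error")
    # validate as a real calendar date
    d <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", year, month, day)),
                  error = function(e) NA)
    if (is.na(d))
      stop_ctg(sprintf("invalid calendar date %d-%d-%d", year, month, day),
               "ctg_date_error")
  } else if (precision == "month") {
    if (is.na(month) || month < 1L || month > 12L)
      stop_ctg("month precision requires a month in 1..12", "ctg_date_error")
    day <- NA_integer_
  } else {
    month <- NA_integer_
    day <- NA_integer_
  }
  structure(list(year = year, month = month, day = day, precision = precision),
            class = "fuzzy_date")
}

# English month names; deliberately not format(x, "%B"), which is
# locale-dependent and would break the registry dialect on non-English
# systems.
.ctg_months <- c("January", "February", "March", "April", "May", "June",
                 "July", "August", "September", "October", "November",
                 "December")

#' Parse a registry date string
#'
#' Accepts the three forms used by the classic ClinicalTrials.gov export
#' ("Month DD, YYYY", "Month YYYY", "YYYY") plus ISO-8601 "YYYY-MM-DD"
#' as a convenience for manifests.
#'
#' @param text A single date string.
#' @return A [fuzzy_date()] with the precision implied by the input form.
#' @examples
#' parse_fuzzy_date("June 6, 2013")
#' parse_fuzzy_date("July 2013")
#' parse_fuzzy_date("2013")
#' @export
parse_fuzzy_date <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  m <- regmatches(txt, regexec("^([A-Za-z]+) ([0-9]{1,2}), ([0-9]{4})$", txt))[[1]]
  if (length(m) == 4L) {
    mon <- match(tolower(m[2]), tolower(.ctg_months))
    if (!is.na(mon))
      return(fuzzy_date(as.integer(m[4]), mon, as.integer(m[3]), "day"))
  }
  m <- regmatches(txt, regexec("^([A-Za-z]+) ([0-9]{4})$", txt))[[1]]
  if (length(m) == 3L) {
    mon <- match(tolower(m[2]), tolower(.ctg_months))
    if (!is.na(mon)) return(fuzzy_date(as.integer(m[3]), mon, precision = "month"))
  }
  if (grepl("^[0-9]{4}$", txt)) return(fuzzy_date(as.integer(txt), precision = "year"))
  m <- regmatches(txt, regexec("^([0-9]{4})-([0-9]{2})-([0-9]{2})$", txt))[[1]]
  if (length(m) == 4L)
    return(fuzzy_date(as.integer(m[2]), as.integer(m[3]), as.integer(m[4]), "day"))
  stop_ctg(sprintf("unrecognized date string: '%s'", text), "ctg_date_error")
}

#' Render a fuzzy date in the registry dialect
#'
#' @param x A [fuzzy_date()].
#' @param ... Unused.
#' @return `"Month DD, YYYY"`, `"Month YYYY"` or `"YYYY"` depending on
#'   precision.
#' @export
format.fuzzy_date <- function(x, ...) {
  switch(x$precision,
         day = sprintf("%s %d, %d", .ctg_months[x$month], x$day, x$year),
         month = sprintf("%s %d", .ctg_months[x$month], x$year),
         year = sprintf("%d", x$year))
}

#' @export
print.fuzzy_date <- function(x, ...) {
  cat(sprintf("<fuzzy_date %s (%s precision)>\n", format(x), x$precision))
  invisible(x)
}

#' Latest-day interpretation of a fuzzy date
#'
#' Maps a fuzzy date onto the last calendar day consistent with it: a
#' day-precision date maps to itself, month precision to the last day of
#' that month, year precision to December 31. This is the conservative
#' reading used throughout the audit: a stated period only counts as
#' "past" once all of it has elapsed.
#'
#' @param d A [fuzzy_date()].
#' @return A `Date`.
#' @export
latest_day <- function(d) {
  stopifnot(inherits(d, "fuzzy_date"))
  switch(d$precision,
         day = as.Date(sprintf("%04d-%02d-%02d", d$year, d$month, d$day)),
         month = {
           first <- as.Date(sprintf("%04d-%02d-01", d$year, d$month))
           seq(first, by = "1 month", length.out = 2L)[2L] - 1L
         },
         year = as.Date(sprintf("%04d-12-31", d$year)))
}

#' Earliest-day interpretation of a fuzzy date
#'
#' Companion to [latest_day()]: the first calendar day consistent with the
#' stated precision. Used to distinguish genuinely future dates from
#' periods that merely straddle a reference date.
#'
#' @inheritParams latest_day
#' @return A `Date`.
#' @export
earliest_day <- function(d) {
  stopifnot(inherits(d, "fuzzy_date"))
  switch(d$precision,
         day = latest_day(d),
         month = as.Date(sprintf("%04d-%02d-01", d$year, d$month)),
         year = as.Date(sprintf("%04d-01-01", d$year)))
}

# classed conditions so callers/tests can target error families
stop_ctg <- function(message, class) {
  stop(errorCondition(message, class = c(class, "ctg_error")))
}
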