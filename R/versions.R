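# Version ordering and validity-period calendar arithmetic.

#' Parse a dotted version string
#'
#' The catalogue version scheme is one to four dot-separated non-negative
#' integers; shorter versions compare as if padded with zeros, so `"1"`,
#' `"1.0"` and `"1.0.0.0"` are equal.
#'
#' @param x Version string.
#' @return Integer vector of length 4 (zero-padded components).
#' @examples
#' parse_version("2.10.0")
#' @export
parse_version <- function(x) {
  x <- as.character(x)
  if (length(x) != 1L || is.na(x) || !grepl("^[0-9]+(\\.[0-9]+){0,3}$", x)) {
    stop_consentry("MalformedVersion", sprintf("'%s' is not a dotted version of 1-4 integers", x))
  }
  n <- as.integer(strsplit(x, ".", fixed = TRUE)[[1]])
  c(n, rep(0L, 4L - length(n)))
}

version_cmp <- function(a, b) {
  d <- parse_version(a) - parse_version(b)
  nz <- which(d != 0L)
  if (length(nz) == 0L) 0L else as.integer(sign(d[nz[1]]))
}

#' Compare two version strings
#'
#' Numeric component-wise comparison, so `"2.10.0"` orders above `"2.9.1"`
#' (unlike lexicographic string order).
#'
#' @param a,b Version strings.
#' @param scheme Version scheme; only `"dotted"` is currently defined.
#' @return `"LT"`, `"EQ"` or `"GT"`.
#' @examples
#' compare_versions("2.10.0", "2.9.1")  # "GT"
#' @export
compare_versions <- function(a, b, scheme = "dotted") {
  if (!identical(scheme, "dotted")) {
    stop_consentry("MalformedVersion", sprintf("unknown version scheme '%s'", scheme))
  }
  c("LT", "EQ", "GT")[version_cmp(a, b) + 2L]
}

#' Parse a validity-period string
#'
#' Periods use a compact ISO-8601-style grammar `p<N>y<N>m<N>d` (case
#' insensitive); each component is optional but at least one must be present
#' and they may not all be zero. `"p1y30d"` is one year and thirty days.
#'
#' @param x Period string, e.g. `"p1y30d"`, `"P18Y"`, `"p6m"`.
#' @return A list of class `"consent_period"` with integer fields `years`,
#'   `months`, `days`.
#' @examples
#' parse_validity_period("p1y30d")
#' @export
parse_validity_period <- function(x) {
  if (!is_string(x)) stop_consentry("MalformedPeriod", "period must be a non-empty string")
  m <- regexec("^[pP](?:([0-9]+)[yY])?(?:([0-9]+)[mM])?(?:([0-9]+)[dD])?$", x)
  g <- regmatches(x, m)[[1]]
  if (length(g) == 0L || all(g[2:4] == "")) {
    stop_consentry("MalformedPeriod", sprintf("'%s' does not match p<N>y<N>m<N>d", x))
  }
  comp <- ifelse(g[2:4] == "", 0L, suppressWarnings(as.integer(g[2:4])))
  if (anyNA(comp) || all(comp == 0L)) {
    stop_consentry("MalformedPeriod", sprintf("'%s' has no positive component", x))
  }
  structure(list(years = comp[1], months = comp[2], days = comp[3]),
            class = "consent_period")
}

#' @export
format.consent_period <- function(x, ...) {
  paste0("p",
         if (x$years > 0) paste0(x$years, "y") else "",
         if (x$months > 0) paste0(x$months, "m") else "",
         if (x$days > 0) paste0(x$days, "d") else "")
}

#' @export
print.consent_period <- function(x, ...) {
  cat(sprintf("<period> %s (%dy %dm %dd)\n", format(x), x$years, x$months, x$days))
  invisible(x)
}

days_in_month <- function(year, month) {
  first_next <- if (month == 12L) as.Date(sprintf("%04d-01-01", year + 1L))
                else as.Date(sprintf("%04d-%02d-01", year, month + 1L))
  as.integer(format(first_next - 1L, "%d"))
}

add_months_clamped <- function(date, n) {
  lt <- as.POSIXlt(date)
  total <- lt$mon + n                 # 0-based month index
  year <- lt$year + 1900L + total %/% 12L
  month <- total %% 12L + 1L
  day <- min(lt$mday, days_in_month(year, month))
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

#' Add a validity period to a date
#'
#' Calendar arithmetic proceeds in order: years, then months, then days.
#' Month-end overflow clamps to the last day of the target month, so
#' Jan 31 + 1 month is Feb 28 (or Feb 29 in a leap year); day addition after
#' that is exact.
#'
#' @param date Anchor `Date` (or ISO string).
#' @param period A [parse_validity_period()] result or period string.
#' @return A `Date`.
#' @examples
#' add_period("2020-01-01", "p1y30d")  # 2021-01-31
#' add_period("2020-01-31", "p1m")     # 2020-02-29
#' @export
add_period <- function(date, period) {
  date <- as_consent_date(date)
  if (!inherits(period, "consent_period")) period <- parse_validity_period(period)
  out <- add_months_clamped(date, period$years * 12L)
  out <- add_months_clamped(out, period$months)
  out + period$days
}
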