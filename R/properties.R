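# Open property vocabulary shared by domains, policies, modules and templates.
#
# Known keys are validated strictly; unknown keys are application-specific
# ("external") properties, stored verbatim and merely flagged in validation
# reports so catalogues remain forward compatible.

.KNOWN_PROPERTY_KEYS <- list(
  VALIDITY_PERIOD = list(
    parse = function(v) parse_validity_period(v),
    description = "validity period anchored at the consent date, e.g. p1y30d"
  ),
  VALIDITY_FIXED_DATE = list(
    parse = function(v) as_consent_date(v, "VALIDITY_FIXED_DATE"),
    description = "fixed expiry date (ISO-8601), e.g. the end of the study"
  ),
  VALIDITY_PERIOD_FROM_BIRTHDATE = list(
    parse = function(v) parse_validity_period(v),
    description = "validity period anchored at the signer's birthdate, e.g. p18y"
  ),
  PERMANENT_WITHDRAWAL = list(
    parse = function(v) parse_property_flag(v),
    description = "when true, re-consent after a withdrawal is rejected at capture"
  ),
  SCAN_SIZE_LIMIT = list(
    parse = function(v) parse_property_int(v),
    description = "maximum scan attachment size in bytes"
  ),
  MANDATORY_SCANS = list(
    parse = function(v) parse_property_flag(v),
    description = "when true, even electronic documents are expected to carry a scan"
  ),
  WEIGHTING = list(
    parse = function(v) {
      if (!v %in% c("DATE_THEN_VERSION", "VERSION_THEN_DATE")) stop("bad weighting")
      v
    },
    description = "version-and-date weighting for latest-document precedence"
  ),
  VERSION_SCHEME = list(
    parse = function(v) { if (!identical(v, "dotted")) stop("bad scheme"); v },
    description = "version scheme for catalogue keys (currently 'dotted')"
  )
)

parse_property_flag <- function(v) {
  v <- tolower(as.character(v))
  if (!v %in% c("true", "false", "1", "0")) stop("not a flag")
  v %in% c("true", "1")
}

parse_property_int <- function(v) {
  if (!grepl("^[0-9]+$", as.character(v))) stop("not a non-negative integer")
  as.integer(v)
}

property_flag <- function(properties, key) {
  v <- properties[[key]]
  if (is.null(v)) FALSE else parse_property_flag(v)
}

#' The documented property-key vocabulary
#'
#' @return Data frame with columns `key` and `description` listing the
#'   property keys the engine itself interprets. Any other key is accepted
#'   and stored verbatim as an application-specific property.
#' @export
known_property_keys <- function() {
  data.frame(
    key = names(.KNOWN_PROPERTY_KEYS),
    description = vapply(.KNOWN_PROPERTY_KEYS, `[[`, "", "description"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Validate a property map
#'
#' Known keys (see [known_property_keys()]) must parse under their grammar;
#' unknown keys are preserved verbatim but reported, so a misspelt known key
#' is visible in the report rather than silently inert.
#'
#' @param properties Named list or character vector of property values.
#' @param strict Raise `InvalidProperty` on an unparseable known key?
#' @return Data frame with one row per property: `key`, `value`, `known`,
#'   `valid`, `message`.
#' @examples
#' validate_properties(list(VALIDITY_PERIOD = "p1y30d", STUDY_ARM = "B"))
#' @export
validate_properties <- function(properties = list(), strict = TRUE) {
  properties <- as.list(properties)
  if (length(properties) > 0 && (is.null(names(properties)) || any(names(properties) == ""))) {
    stop_consentry("InvalidProperty", "properties must be a named map")
  }
  rows <- lapply(names(properties), function(k) {
    v <- as.character(properties[[k]])
    spec <- .KNOWN_PROPERTY_KEYS[[k]]
    if (is.null(spec)) {
      data.frame(key = k, value = v, known = FALSE, valid = TRUE,
                 message = "unknown key, stored verbatim", stringsAsFactors = FALSE)
    } else {
      ok <- !inherits(tryCatch(spec$parse(v), error = function(e) e), "error")
      data.frame(key = k, value = v, known = TRUE, valid = ok,
                 message = if (ok) "" else sprintf("value '%s' invalid for %s", v, k),
                 stringsAsFactors = FALSE)
    }
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), value = character(), known = logical(),
               valid = logical(), message = character(), stringsAsFactors = FALSE)
  if (strict && any(!report$valid)) {
    bad <- report$key[!report$valid][1]
    stop_consentry("InvalidProperty",
                   sprintf("property %s: %s", bad, report$message[!report$valid][1]))
  }
  report
}

normalize_properties <- function(properties = list()) {
  properties <- as.list(properties)
  lapply(properties, as.character)
}
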