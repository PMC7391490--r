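# Internal helpers: condition signalling, keys, signers, date coercion.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All engine errors carry a named condition class (e.g. "DuplicateDomain")
# plus the umbrella class "consentry_error", so callers can catch either the
# specific failure or any engine failure.
stop_consentry <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "consentry_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

#' Build a versioned entity key
#'
#' Policies, modules and templates are identified by a (domain, name, version)
#' triple; all three components are required and version strings must parse
#' under the dotted-integer scheme when the entity is defined.
#'
#' @param domain Domain name.
#' @param name Entity name within the domain.
#' @param version Version string, e.g. `"1.0"` or `"2.10.0"`.
#' @param kind One of `"policy"`, `"module"`, `"template"`.
#' @return A list of class `"consent_key"` with fields `domain`, `name`,
#'   `version` and `kind`.
#' @examples
#' consent_key("study", "data_collection", "1.0", "policy")
#' @export
consent_key <- function(domain, name, version, kind = c("policy", "module", "template")) {
  kind <- match.arg(kind)
  if (!is_string(domain) || !is_string(name) || !is_string(as.character(version))) {
    stop_consentry("MalformedKey", "a key needs non-empty domain, name and version")
  }
  structure(
    list(domain = domain, name = name, version = as.character(version), kind = kind),
    class = "consent_key"
  )
}

#' @export
print.consent_key <- function(x, ...) {
  cat(sprintf("<%s key> %s\n", x$kind, key_string(x)))
  invisible(x)
}

#' Canonical string form of a key
#'
#' @param key A [consent_key()] or a `"domain/name/version"` string.
#' @return A single string `"domain/name/version"`.
#' @export
key_string <- function(key) {
  if (is.character(key)) return(key)
  paste(key$domain, key$name, key$version, sep = "/")
}

#' Parse a `"domain/name/version"` string into a key
#'
#' @param x Key string with exactly three `/`-separated components.
#' @inheritParams consent_key
#' @return A [consent_key()].
#' @export
parse_key <- function(x, kind = c("policy", "module", "template")) {
  kind <- match.arg(kind)
  if (inherits(x, "consent_key")) {
    x$kind <- kind
    return(x)
  }
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop_consentry("MalformedKey", sprintf("expected 'domain/name/version', got '%s'", x))
  }
  consent_key(parts[1], parts[2], parts[3], kind)
}

as_key <- function(x, kind) {
  if (inherits(x, "consent_key")) x else parse_key(x, kind)
}

#' Participant identifier
#'
#' A signer is identified by an identifier type registered with the domain
#' (typically `"pseudonym"`, issued by a trusted third party) and an opaque
#' value.
#'
#' @param id_type Identifier-type name registered with the domain.
#' @param value Opaque identifier string.
#' @return A list of class `"signer_id"`.
#' @examples
#' signer_id("pseudonym", "P-0001")
#' @export
signer_id <- function(id_type, value) {
  if (!is_string(id_type) || !is_string(value)) {
    stop_consentry("MalformedSignerId", "signer needs non-empty id_type and value")
  }
  structure(list(id_type = id_type, value = value), class = "signer_id")
}

as_signer <- function(x) {
  if (inherits(x, "signer_id")) return(x)
  if (is_string(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L) return(signer_id(parts[1], parts[2]))
    return(signer_id("pseudonym", x))
  }
  stop_consentry("MalformedSignerId", "cannot interpret signer identifier")
}

signer_string <- function(signer) paste(signer$id_type, signer$value, sep = ":")

# Strict ISO-8601 date coercion; everything user-facing funnels through here
# so the CLI and JSON dispatcher can pass plain strings.
as_consent_date <- function(x, what = "date") {
  if (inherits(x, "Date")) {
    if (length(x) != 1L || is.na(x)) stop_consentry("MalformedDate", sprintf("invalid %s", what))
    return(x)
  }
  d <- tryCatch(as.Date(as.character(x), format = "%Y-%m-%d"), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) {
    stop_consentry("MalformedDate", sprintf("%s must be an ISO-8601 date (YYYY-MM-DD), got '%s'", what, x))
  }
  d
}

iso_date <- function(x) if (is.null(x)) NA_character_ else format(x, "%Y-%m-%d")
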