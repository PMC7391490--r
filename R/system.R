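# The consent store: an environment-backed object holding the catalogue,
# the append-only document history, signer birthdates, audit log and
# engine configuration. Operations mutate it in place (reference semantics,
# as a service backend would) and return the affected entity.

#' Create an empty consent management store
#'
#' The store holds the versioned catalogue (domains, policies, modules,
#' templates), the append-only consent document history, signer birthdates
#' for birthdate-anchored validity, the audit log, and the engine
#' configuration. It has reference semantics: all operations take it as
#' their first argument and modify it in place.
#'
#' @param config Named list overriding engine defaults:
#'   `weighting` (`"DATE_THEN_VERSION"` or `"VERSION_THEN_DATE"`),
#'   `unknown_as_decline` (logical), `ignore_version_number` (logical),
#'   `allow_incomplete_mandatory` (logical; archive instead of reject a
#'   capture whose mandatory module was not accepted).
#' @return An object of class `"consent_system"`.
#' @examples
#' sys <- consent_system()
#' create_domain(sys, "study", "Example study")
#' @export
consent_system <- function(config = list()) {
  defaults <- list(
    weighting = "DATE_THEN_VERSION",
    unknown_as_decline = FALSE,
    ignore_version_number = FALSE,
    allow_incomplete_mandatory = FALSE
  )
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop_consentry("ConfigError", sprintf("unknown config key '%s'", bad[1]))
  defaults[names(config)] <- config
  if (!defaults$weighting %in% c("DATE_THEN_VERSION", "VERSION_THEN_DATE")) {
    stop_consentry("ConfigError", "weighting must be DATE_THEN_VERSION or VERSION_THEN_DATE")
  }
  sys <- new.env(parent = emptyenv())
  sys$domains <- list()
  sys$policies <- list()
  sys$modules <- list()
  sys$templates <- list()
  sys$documents <- list()     # named by document_id, insertion order preserved
  sys$birthdates <- list()    # signer string -> Date
  sys$audit <- list()
  sys$config <- defaults
  sys$doc_counter <- 0L
  class(sys) <- "consent_system"
  sys
}

#' @export
print.consent_system <- function(x, ...) {
  cat("<consent_system>\n")
  cat(sprintf("  domains:   %d\n", length(x$domains)))
  cat(sprintf("  policies:  %d   modules: %d   templates: %d\n",
              length(x$policies), length(x$modules), length(x$templates)))
  cat(sprintf("  documents: %d   audit records: %d\n",
              length(x$documents), length(x$audit)))
  cat(sprintf("  weighting: %s   unknown_as_decline: %s\n",
              x$config$weighting, x$config$unknown_as_decline))
  invisible(x)
}

assert_system <- function(sys) {
  if (!inherits(sys, "consent_system")) {
    stop_consentry("ConfigError", "first argument must be a consent_system")
  }
  invisible(sys)
}

#' Read or change engine configuration
#'
#' @param sys A [consent_system()].
#' @param ... For `set_config`, `key = value` pairs to change.
#' @return `get_config` returns the configuration list; `set_config` returns
#'   the updated list invisibly.
#' @export
get_config <- function(sys) {
  assert_system(sys)
  sys$config
}

#' @rdname get_config
#' @export
set_config <- function(sys, ...) {
  assert_system(sys)
  changes <- list(...)
  bad <- setdiff(names(changes), names(sys$config))
  if (length(bad)) stop_consentry("ConfigError", sprintf("unknown config key '%s'", bad[1]))
  sys$config[names(changes)] <- changes
  invisible(sys$config)
}

# ---- full-state persistence (text JSON; scans base64-encoded) --------------

# strip S3 classes so jsonlite serialises plain lists
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

serialize_system <- function(sys) {
  assert_system(sys)
  doc_to_list <- function(d) {
    d$consent_date <- iso_date(d$consent_date)
    d$capture_timestamp <- format(d$capture_timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    if (!is.null(d$invalidation)) d$invalidation$date <- iso_date(d$invalidation$date)
    d$scans <- lapply(d$scans, function(s) {
      list(blob = jsonlite::base64_enc(s$blob), content_type = s$content_type,
           uploaded_at = format(s$uploaded_at, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"))
    })
    d$free_text_values <- lapply(d$free_text_values, function(v) {
      if (inherits(v, "Date")) iso_date(v) else v
    })
    d
  }
  unclass_deep(list(
    format = "consentry-store",
    schema_version = "1.0",
    config = sys$config,
    domains = unname(lapply(sys$domains, function(d) {
      if (!is.null(d$logo)) d$logo <- jsonlite::base64_enc(d$logo)
      d
    })),
    policies = unname(sys$policies),
    modules = unname(sys$modules),
    templates = unname(sys$templates),
    documents = unname(lapply(sys$documents, doc_to_list)),
    birthdates = lapply(sys$birthdates, iso_date),
    audit = lapply(sys$audit, function(a) {
      a$timestamp <- format(a$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
      a
    }),
    doc_counter = sys$doc_counter
  ))
}

#' Save / load the full store state
#'
#' The complete store (catalogue, documents, birthdates, audit log and
#' configuration) round-trips through a single JSON document; scan blobs and
#' logos are base64-encoded. This is the persistence format the CLI uses
#' between invocations.
#'
#' @param sys A [consent_system()].
#' @param path File path; for `load_system` a missing file yields a fresh
#'   empty store.
#' @return `save_system` returns `path` invisibly; `load_system` returns a
#'   [consent_system()].
#' @export
save_system <- function(sys, path) {
  state <- serialize_system(sys)
  jsonlite::write_json(state, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname save_system
#' @export
load_system <- function(path) {
  if (!file.exists(path)) return(consent_system())
  state <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(state$format, "consentry-store")) {
    stop_consentry("ConfigError", sprintf("'%s' is not a consentry store file", path))
  }
  sys <- consent_system(config = state$config)
  for (d in state$domains) {
    if (!is.null(d$logo)) d$logo <- jsonlite::base64_dec(d$logo)
    d$properties <- lapply(d$properties, as.character)
    d$signer_id_types <- as.character(unlist(d$signer_id_types))
    sys$domains[[d$name]] <- d
  }
  fix_key <- function(k, kind) consent_key(k$domain, k$name, k$version, kind)
  for (p in state$policies) {
    p$key <- fix_key(p$key, "policy")
    p$properties <- lapply(p$properties, as.character)
    sys$policies[[key_string(p$key)]] <- p
  }
  for (m in state$modules) {
    m$key <- fix_key(m$key, "module")
    m$policies <- lapply(m$policies, fix_key, kind = "policy")
    m$properties <- lapply(m$properties, as.character)
    sys$modules[[key_string(m$key)]] <- m
  }
  for (tpl in state$templates) {
    tpl$key <- fix_key(tpl$key, "template")
    tpl$module_assignments <- lapply(tpl$module_assignments, function(a) {
      a$module <- fix_key(a$module, "module")
      a$mandatory <- isTRUE(a$mandatory)
      a$display_order <- as.integer(a$display_order)
      a
    })
    tpl$free_text_defs <- lapply(tpl$free_text_defs, function(f) {
      free_text_field(f$name, f$value_type, isTRUE(f$required), f$label %||% f$name)
    })
    tpl$properties <- lapply(tpl$properties, as.character)
    sys$templates[[key_string(tpl$key)]] <- tpl
  }
  for (doc in state$documents) {
    doc$signer <- signer_id(doc$signer$id_type, doc$signer$value)
    doc$template <- fix_key(doc$template, "template")
    doc$consent_date <- as_consent_date(doc$consent_date)
    doc$capture_timestamp <- as.POSIXct(doc$capture_timestamp,
                                        format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    if (!is.null(doc$invalidation)) {
      doc$invalidation$date <- as_consent_date(doc$invalidation$date)
    }
    doc$policy_states <- lapply(doc$policy_states, as.character)
    doc$scans <- lapply(doc$scans, function(s) {
      list(blob = jsonlite::base64_dec(s$blob), content_type = s$content_type,
           uploaded_at = as.POSIXct(s$uploaded_at, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
    })
    class(doc) <- "consent_document"
    sys$documents[[doc$document_id]] <- doc
  }
  sys$birthdates <- lapply(state$birthdates, as_consent_date)
  sys$audit <- lapply(state$audit, function(a) {
    a$timestamp <- as.POSIXct(a$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    a
  })
  sys$doc_counter <- as.integer(state$doc_counter)
  sys
}
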