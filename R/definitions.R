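# Definition-file exchange: a domain's full catalogue as one JSON document
# with top-level keys domain / policies / modules / templates. The format is
# described by the schema shipped in inst/extdata/definitions-schema.json and
# round-trips losslessly (export then import reproduces the catalogue).

key_to_list <- function(k) list(domain = k$domain, name = k$name, version = k$version)

#' Export a domain's catalogue as a definition document
#'
#' @param sys A [consent_system()].
#' @param domain Domain name.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON text (a single string), invisibly when `path` is given.
#' @export
export_definitions <- function(sys, domain, path = NULL) {
  assert_system(sys)
  d <- require_domain(sys, domain)
  doc <- list(
    format = "consentry-definitions",
    schema_version = "1.0",
    domain = list(
      name = d$name, label = d$label, properties = d$properties,
      signer_id_types = as.list(d$signer_id_types),
      logo = if (is.null(d$logo)) NULL else jsonlite::base64_enc(d$logo),
      deprecated = isTRUE(d$deprecated)
    ),
    policies = lapply(list_policies(sys, domain, include_deprecated = TRUE), function(p) {
      list(key = key_to_list(p$key), label = p$label, properties = p$properties,
           lifecycle = p$lifecycle, deprecated = isTRUE(p$deprecated))
    }),
    modules = lapply(list_modules(sys, domain, include_deprecated = TRUE), function(m) {
      list(key = key_to_list(m$key), title = m$title, text = m$text,
           policies = lapply(m$policies, key_string),
           properties = m$properties, lifecycle = m$lifecycle,
           deprecated = isTRUE(m$deprecated))
    }),
    templates = lapply(list_templates(sys, domain, include_deprecated = TRUE), function(tpl) {
      list(key = key_to_list(tpl$key), header = tpl$header, footer = tpl$footer,
           module_assignments = lapply(tpl$module_assignments, function(a) {
             list(module = key_string(a$module), mandatory = a$mandatory,
                  display_order = a$display_order)
           }),
           free_text_defs = lapply(tpl$free_text_defs, unclass),
           properties = tpl$properties, template_kind = tpl$template_kind,
           lifecycle = tpl$lifecycle, deprecated = isTRUE(tpl$deprecated))
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Import a definition document into a store
#'
#' Recreates the domain and its policies, modules and templates, restoring
#' lifecycle (DRAFT/FINALIZED) and deprecation flags. One audit record is
#' written for the whole import.
#'
#' @param sys A [consent_system()].
#' @param input JSON text, a parsed list, or a file path.
#' @param actor Audit actor.
#' @return The imported domain name, invisibly.
#' @export
import_definitions <- function(sys, input, actor = "system") {
  assert_system(sys)
  doc <- if (is.list(input)) input
         else if (is_string(input) && file.exists(input)) jsonlite::read_json(input, simplifyVector = FALSE)
         else jsonlite::parse_json(input, simplifyVector = FALSE)
  if (!identical(doc$format, "consentry-definitions")) {
    stop_consentry("MalformedDefinitions", "not a consentry definition document")
  }
  dname <- doc$domain$name
  with_audit(sys, "import_definitions", dname, actor, {
    create_domain_quiet <- function() {
      if (!is.null(sys$domains[[dname]])) {
        stop_consentry("DuplicateDomain", sprintf("domain '%s' already exists", dname))
      }
      d <- list(
        name = dname, label = doc$domain$label %||% dname,
        properties = lapply(doc$domain$properties, as.character),
        signer_id_types = as.character(unlist(doc$domain$signer_id_types %||% list("pseudonym"))),
        logo = if (is.null(doc$domain$logo)) NULL else jsonlite::base64_dec(doc$domain$logo),
        deprecated = isTRUE(doc$domain$deprecated)
      )
      validate_properties(d$properties, strict = TRUE)
      sys$domains[[dname]] <- d
    }
    create_domain_quiet()
    restore <- function(entity, kind, lifecycle, deprecated) {
      entity$lifecycle <- lifecycle %||% "DRAFT"
      entity$deprecated <- isTRUE(deprecated)
      store_entity(sys, entity, kind)
    }
    for (p in doc$policies) {
      e <- define_policy_core(sys, consent_key(p$key$domain, p$key$name, p$key$version, "policy"),
                              p$label, p$properties %||% list())
      restore(e, "policy", p$lifecycle, p$deprecated)
    }
    for (m in doc$modules) {
      e <- define_module_core(sys, consent_key(m$key$domain, m$key$name, m$key$version, "module"),
                              m$title, m$text %||% "",
                              lapply(m$policies, parse_key, kind = "policy"),
                              m$properties %||% list())
      restore(e, "module", m$lifecycle, m$deprecated)
    }
    for (tpl in doc$templates) {
      e <- define_template_core(
        sys, consent_key(tpl$key$domain, tpl$key$name, tpl$key$version, "template"),
        tpl$header %||% "", tpl$footer %||% "",
        lapply(tpl$module_assignments, function(a) {
          list(module = parse_key(a$module, "module"),
               mandatory = isTRUE(a$mandatory),
               display_order = as.integer(a$display_order))
        }),
        lapply(tpl$free_text_defs, function(f) {
          free_text_field(f$name, f$value_type, isTRUE(f$required), f$label %||% f$name)
        }),
        tpl$properties %||% list(),
        tpl$template_kind %||% "CONSENT"
      )
      restore(e, "template", tpl$lifecycle, tpl$deprecated)
    }
    invisible(dname)
  })
}

#' The definition-document schema
#'
#' @return The JSON-schema description of the definition exchange format, as
#'   a parsed list.
#' @export
definitions_schema <- function() {
  path <- system.file("extdata", "definitions-schema.json", package = "consentry")
  jsonlite::read_json(path, simplifyVector = FALSE)
}
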