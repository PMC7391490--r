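# Catalogue of contextual domains and the versioned policy/module/template
# hierarchy. Entities start life as DRAFT; once FINALIZED (explicitly, or
# implicitly the first time a template is used by a capture) their content is
# immutable and any change requires a new version.

slot_for <- function(kind) {
  switch(kind, policy = "policies", module = "modules", template = "templates",
         stop_consentry("UnknownEntity", sprintf("no entity kind '%s'", kind)))
}

lookup_entity <- function(sys, key, kind) {
  sys[[slot_for(kind)]][[key_string(key)]]
}

require_domain <- function(sys, name) {
  d <- sys$domains[[name]]
  if (is.null(d)) stop_consentry("UnknownDomain", sprintf("domain '%s' is not registered", name))
  d
}

require_entity <- function(sys, key, kind) {
  e <- lookup_entity(sys, key, kind)
  if (is.null(e)) {
    stop_consentry(switch(kind, policy = "UnknownPolicy", module = "UnknownModule",
                          template = "UnknownTemplate"),
                   sprintf("%s '%s' is not registered", kind, key_string(key)))
  }
  e
}

store_entity <- function(sys, entity, kind) {
  sys[[slot_for(kind)]][[key_string(entity$key)]] <- entity
  entity
}

validate_key_for_domain <- function(sys, key, kind) {
  require_domain(sys, key$domain)
  parse_version(key$version)  # MalformedVersion if the scheme is violated
  if (!is.null(lookup_entity(sys, key, kind))) {
    stop_consentry("DuplicateKey",
                   sprintf("%s '%s' already exists", kind, key_string(key)))
  }
  invisible(key)
}

# ---- domains ----------------------------------------------------------------

#' Register a contextual domain
#'
#' Domains are the organisational unit (a project, study site or institution)
#' owning policies, modules, templates, configuration properties and the
#' identifier types under which participants are filed.
#'
#' @param sys A [consent_system()].
#' @param name Unique domain name.
#' @param label Display label.
#' @param properties Named property map; known keys (see
#'   [known_property_keys()]) are validated, unknown keys stored verbatim.
#' @param signer_id_types Identifier-type names accepted for signers.
#' @param logo Optional raw vector (PNG/JPEG blob), stored opaque.
#' @param actor Actor recorded in the audit log.
#' @return The domain record, invisibly.
#' @examples
#' sys <- consent_system()
#' create_domain(sys, "study_a", "Study A",
#'               properties = list(VALIDITY_PERIOD = "p1y30d"))
#' @export
create_domain <- function(sys, name, label = name, properties = list(),
                          signer_id_types = "pseudonym", logo = NULL,
                          actor = "system") {
  assert_system(sys)
  with_audit(sys, "create_domain", name, actor, {
    if (!is_string(name)) stop_consentry("InvalidProperty", "domain name must be a non-empty string")
    if (!is.null(sys$domains[[name]])) {
      stop_consentry("DuplicateDomain", sprintf("domain '%s' already exists", name))
    }
    validate_properties(properties, strict = TRUE)
    if (!is.null(logo) && !is.raw(logo)) {
      stop_consentry("InvalidProperty", "logo must be a raw blob (PNG/JPEG)")
    }
    d <- list(name = name, label = label,
              properties = normalize_properties(properties),
              signer_id_types = as.character(signer_id_types),
              logo = logo, deprecated = FALSE)
    sys$domains[[name]] <- d
    invisible(d)
  })
}

#' Fetch a domain record
#' @inheritParams create_domain
#' @return The domain record.
#' @export
get_domain <- function(sys, name) {
  assert_system(sys)
  require_domain(sys, name)
}

#' List registered domains
#' @inheritParams create_domain
#' @param include_deprecated Include deprecated domains?
#' @return Data frame with columns `name`, `label`, `deprecated`.
#' @export
list_domains <- function(sys, include_deprecated = FALSE) {
  assert_system(sys)
  ds <- sys$domains
  if (!include_deprecated) ds <- Filter(function(d) !isTRUE(d$deprecated), ds)
  ds <- ds[order(names(ds))]
  data.frame(
    name = vapply(ds, `[[`, "", "name"),
    label = vapply(ds, `[[`, "", "label"),
    deprecated = vapply(ds, function(d) isTRUE(d$deprecated), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Set or change a domain property
#'
#' Domain properties configure engine behaviour for the whole domain
#' (validity, scan limits, permanent withdrawal, weighting). Domains stay
#' mutable at this level: properties govern future operations, they do not
#' alter stored documents.
#'
#' @inheritParams create_domain
#' @param key Property key.
#' @param value Property value (string form).
#' @return The updated domain, invisibly.
#' @export
set_domain_property <- function(sys, name, key, value, actor = "system") {
  assert_system(sys)
  with_audit(sys, "set_domain_property", paste0(name, "#", key), actor, {
    d <- require_domain(sys, name)
    validate_properties(stats::setNames(list(value), key), strict = TRUE)
    d$properties[[key]] <- as.character(value)
    sys$domains[[name]] <- d
    invisible(d)
  })
}

#' Read a single domain property
#' @inheritParams set_domain_property
#' @return The property value as a string, or `NULL` when unset.
#' @export
get_domain_property <- function(sys, name, key) {
  assert_system(sys)
  require_domain(sys, name)$properties[[key]]
}

#' Register an additional signer identifier type for a domain
#' @inheritParams create_domain
#' @param id_type Identifier-type name (e.g. `"case_number"`).
#' @return The updated domain, invisibly.
#' @export
register_signer_id_type <- function(sys, name, id_type, actor = "system") {
  assert_system(sys)
  with_audit(sys, "register_signer_id_type", paste0(name, "#", id_type), actor, {
    d <- require_domain(sys, name)
    d$signer_id_types <- union(d$signer_id_types, id_type)
    sys$domains[[name]] <- d
    invisible(d)
  })
}

#' Deprecate a domain
#'
#' Deprecation hides a domain from default listings; nothing is deleted, so
#' the audit trail and document history stay intact.
#'
#' @inheritParams create_domain
#' @return The updated domain, invisibly.
#' @export
deprecate_domain <- function(sys, name, actor = "system") {
  assert_system(sys)
  with_audit(sys, "deprecate_domain", name, actor, {
    d <- require_domain(sys, name)
    d$deprecated <- TRUE
    sys$domains[[name]] <- d
    invisible(d)
  })
}

# ---- policies ---------------------------------------------------------------

define_policy_core <- function(sys, key, label, properties = list()) {
  key <- as_key(key, "policy")
  validate_key_for_domain(sys, key, "policy")
  validate_properties(properties, strict = TRUE)
  if (!is_string(label)) stop_consentry("InvalidProperty", "policy label must be a non-empty string")
  p <- list(key = key, label = label, properties = normalize_properties(properties),
            lifecycle = "DRAFT", deprecated = FALSE)
  store_entity(sys, p, "policy")
}

#' Define a consent policy
#'
#' A policy is the atomic unit of consent: one permit/deny decision (for
#' example "allow data collection" or "store biosamples"). Policies are
#' version-specific; the label is the question text shown to the
#' participant.
#'
#' @param sys A [consent_system()].
#' @param key A [consent_key()] or `"domain/name/version"` string.
#' @param label Question text shown to the participant.
#' @param properties Property map (validity specs etc.).
#' @param actor Audit actor.
#' @return The stored DRAFT policy, invisibly.
#' @export
define_policy <- function(sys, key, label, properties = list(), actor = "system") {
  assert_system(sys)
  key <- as_key(key, "policy")
  with_audit(sys, "define_policy", key_string(key), actor,
             invisible(define_policy_core(sys, key, label, properties)))
}

#' Fetch a policy
#' @inheritParams define_policy
#' @return The policy record.
#' @export
get_policy <- function(sys, key) {
  assert_system(sys)
  require_entity(sys, as_key(key, "policy"), "policy")
}

# ---- modules ----------------------------------------------------------------

define_module_core <- function(sys, key, title, text = "", policy_keys,
                               properties = list()) {
  key <- as_key(key, "module")
  validate_key_for_domain(sys, key, "module")
  validate_properties(properties, strict = TRUE)
  if (length(policy_keys) == 0L) {
    stop_consentry("EmptyModule", "a module must aggregate at least one policy")
  }
  pk <- lapply(policy_keys, as_key, kind = "policy")
  ks <- vapply(pk, key_string, "")
  if (anyDuplicated(ks)) {
    stop_consentry("DuplicatePolicyInModule",
                   sprintf("policy '%s' listed twice", ks[duplicated(ks)][1]))
  }
  for (k in pk) {
    if (k$domain != key$domain) {
      stop_consentry("UnknownPolicy",
                     sprintf("policy '%s' is not in domain '%s'", key_string(k), key$domain))
    }
    require_entity(sys, k, "policy")
  }
  m <- list(key = key, title = title, text = text, policies = pk,
            properties = normalize_properties(properties),
            lifecycle = "DRAFT", deprecated = FALSE)
  store_entity(sys, m, "module")
}

#' Define a consent module
#'
#' A module aggregates logically coherent policies that are presented and
#' answered together — e.g. a "processing research data" module combining
#' the policies for collecting, transferring and storing health information.
#' Policy order is preserved.
#'
#' @inheritParams define_policy
#' @param title Module title.
#' @param text Formatted descriptive text shown with the module.
#' @param policy_keys Ordered list of policy keys (objects or strings), all
#'   from the module's own domain, duplicate-free, non-empty.
#' @return The stored DRAFT module, invisibly.
#' @export
define_module <- function(sys, key, title, text = "", policy_keys,
                          properties = list(), actor = "system") {
  assert_system(sys)
  key <- as_key(key, "module")
  with_audit(sys, "define_module", key_string(key), actor,
             invisible(define_module_core(sys, key, title, text, policy_keys, properties)))
}

#' Fetch a module
#' @inheritParams define_policy
#' @return The module record.
#' @export
get_module <- function(sys, key) {
  assert_system(sys)
  require_entity(sys, as_key(key, "module"), "module")
}

# ---- templates --------------------------------------------------------------

#' Declare a free-text field for a template
#'
#' @param name Field identifier, unique within the template.
#' @param value_type One of `DATE`, `BOOLEAN`, `STRING`, `INTEGER`, `DOUBLE`.
#' @param required Must a value be supplied at capture?
#' @param label Display label.
#' @return A list of class `"free_text_def"`.
#' @examples
#' free_text_field("treatment_facility", "STRING")
#' @export
free_text_field <- function(name, value_type = c("STRING", "DATE", "BOOLEAN", "INTEGER", "DOUBLE"),
                            required = FALSE, label = name) {
  value_type <- match.arg(toupper(value_type), c("STRING", "DATE", "BOOLEAN", "INTEGER", "DOUBLE"))
  if (!is_string(name)) stop_consentry("FreeTextValidation", "field name must be a non-empty string")
  structure(list(name = name, value_type = value_type,
                 required = isTRUE(required), label = label),
            class = "free_text_def")
}

normalize_assignment <- function(a, i) {
  if (inherits(a, "consent_key") || is.character(a)) {
    a <- list(module = a)
  }
  list(module = as_key(a$module, "module"),
       mandatory = isTRUE(a$mandatory),
       display_order = as.integer(a$display_order %||% i))
}

define_template_core <- function(sys, key, header = "", footer = "",
                                 module_assignments, free_text_defs = list(),
                                 properties = list(),
                                 template_kind = c("CONSENT", "WITHDRAWAL")) {
  key <- as_key(key, "template")
  template_kind <- match.arg(template_kind)
  validate_key_for_domain(sys, key, "template")
  validate_properties(properties, strict = TRUE)
  if (length(module_assignments) == 0L) {
    stop_consentry("EmptyTemplate", "a template consists of at least one module")
  }
  assignments <- Map(normalize_assignment, module_assignments,
                     seq_along(module_assignments))
  seen <- character()   # policy names already contributed by earlier modules
  for (a in assignments) {
    if (a$module$domain != key$domain) {
      stop_consentry("UnknownModule",
                     sprintf("module '%s' is not in domain '%s'",
                             key_string(a$module), key$domain))
    }
    m <- require_entity(sys, a$module, "module")
    # no-contradiction rule: one policy name may answer at most once per form,
    # regardless of version — two versions of the same question still contradict
    pnames <- vapply(m$policies, `[[`, "", "name")
    clash <- intersect(c(pnames[duplicated(pnames)], pnames), seen)
    if (anyDuplicated(pnames) || length(clash)) {
      bad <- if (length(clash)) clash[1] else pnames[duplicated(pnames)][1]
      stop_consentry("PolicyAppearsTwice",
                     sprintf("policy '%s' appears in more than one assigned module", bad))
    }
    seen <- c(seen, pnames)
  }
  defs <- lapply(free_text_defs, function(f) {
    if (inherits(f, "free_text_def")) f
    else free_text_field(f$name, f$value_type, isTRUE(f$required), f$label %||% f$name)
  })
  fnames <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(fnames)) {
    stop_consentry("FreeTextValidation",
                   sprintf("free-text field '%s' declared twice", fnames[duplicated(fnames)][1]))
  }
  tpl <- list(key = key, header = header, footer = footer,
              module_assignments = unname(assignments),
              free_text_defs = unname(defs),
              properties = normalize_properties(properties),
              template_kind = template_kind,
              lifecycle = "DRAFT", deprecated = FALSE)
  store_entity(sys, tpl, "template")
}

#' Define a consent template
#'
#' A template is one versioned consent form: an introductory header, an
#' ordered list of module assignments (each optionally flagged mandatory,
#' e.g. as a necessary condition for study participation), a closing footer,
#' and optional typed free-text fields. Across all assigned modules each
#' policy name may occur only once, so one form can never ask the same
#' question twice with potentially contradictory answers.
#'
#' @inheritParams define_policy
#' @param header,footer Introductory and closing text.
#' @param module_assignments List of module keys, or lists
#'   `list(module =, mandatory =, display_order =)`.
#' @param free_text_defs List of [free_text_field()] definitions.
#' @param template_kind `"CONSENT"` or `"WITHDRAWAL"`.
#' @return The stored DRAFT template, invisibly.
#' @export
define_template <- function(sys, key, header = "", footer = "",
                            module_assignments, free_text_defs = list(),
                            properties = list(),
                            template_kind = c("CONSENT", "WITHDRAWAL"),
                            actor = "system") {
  assert_system(sys)
  key <- as_key(key, "template")
  with_audit(sys, "define_template", key_string(key), actor,
             invisible(define_template_core(sys, key, header, footer,
                                            module_assignments, free_text_defs,
                                            properties, template_kind)))
}

#' Fetch a template
#' @inheritParams define_policy
#' @return The template record.
#' @export
get_template <- function(sys, key) {
  assert_system(sys)
  require_entity(sys, as_key(key, "template"), "template")
}

# All distinct policies of a template, in module order.
template_policies <- function(sys, tpl) {
  out <- list()
  for (a in tpl$module_assignments) {
    m <- require_entity(sys, a$module, "module")
    for (p in m$policies) out[[key_string(p)]] <- p
  }
  out
}

order_by_name_version <- function(names, versions) {
  vm <- t(vapply(versions, parse_version, integer(4)))
  order(names, vm[, 1], vm[, 2], vm[, 3], vm[, 4])
}

list_entities <- function(sys, domain, kind, include_deprecated = FALSE) {
  require_domain(sys, domain)
  es <- Filter(function(e) e$key$domain == domain &&
                 (include_deprecated || !isTRUE(e$deprecated)),
               sys[[slot_for(kind)]])
  es <- unname(es)
  if (length(es) == 0L) return(es)
  es[order_by_name_version(vapply(es, function(e) e$key$name, ""),
                           vapply(es, function(e) e$key$version, ""))]
}

#' List catalogue entities of a domain
#'
#' All versions are returned, ordered by name and then numeric version (so
#' `2.10.0` lists after `2.9.1`). Deprecated entities are hidden unless
#' requested.
#'
#' @inheritParams define_policy
#' @param domain Domain name.
#' @param include_deprecated Include deprecated entries?
#' @return A list of entity records.
#' @export
list_templates <- function(sys, domain, include_deprecated = FALSE) {
  assert_system(sys)
  list_entities(sys, domain, "template", include_deprecated)
}

#' @rdname list_templates
#' @export
list_policies <- function(sys, domain, include_deprecated = FALSE) {
  assert_system(sys)
  list_entities(sys, domain, "policy", include_deprecated)
}

#' @rdname list_templates
#' @export
list_modules <- function(sys, domain, include_deprecated = FALSE) {
  assert_system(sys)
  list_entities(sys, domain, "module", include_deprecated)
}

# ---- lifecycle --------------------------------------------------------------

assert_draft <- function(entity, kind) {
  if (!identical(entity$lifecycle, "DRAFT")) {
    stop_consentry("ImmutableEntity",
                   sprintf("%s '%s' is FINALIZED; changes require a new version",
                           kind, key_string(entity$key)))
  }
  invisible(entity)
}

finalize_core <- function(sys, key, kind) {
  e <- require_entity(sys, key, kind)
  if (identical(e$lifecycle, "FINALIZED")) return(e)  # idempotent
  e$lifecycle <- "FINALIZED"
  store_entity(sys, e, kind)
  # finalizing a container freezes everything it embeds
  if (kind == "template") {
    for (a in e$module_assignments) finalize_core(sys, a$module, "module")
  } else if (kind == "module") {
    for (p in e$policies) finalize_core(sys, p, "policy")
  }
  e
}

#' Finalize a catalogue entity
#'
#' Finalization freezes an entity's content: the wording already consented to
#' by participants can never change, any edit requires a new version.
#' Finalizing a template transitively finalizes its modules and their
#' policies. Templates are also finalized implicitly the first time a
#' consent document references them. Idempotent.
#'
#' @inheritParams define_policy
#' @param kind `"policy"`, `"module"` or `"template"`.
#' @return The finalized entity, invisibly.
#' @export
finalize <- function(sys, key, kind = c("template", "module", "policy"),
                     actor = "system") {
  assert_system(sys)
  kind <- match.arg(kind)
  key <- as_key(key, kind)
  with_audit(sys, "finalize", key_string(key), actor,
             invisible(finalize_core(sys, key, kind)))
}

#' Is an entity finalized?
#' @inheritParams finalize
#' @return Logical scalar.
#' @export
is_finalized <- function(sys, key, kind = c("template", "module", "policy")) {
  assert_system(sys)
  kind <- match.arg(kind)
  identical(require_entity(sys, as_key(key, kind), kind)$lifecycle, "FINALIZED")
}

#' Update a DRAFT policy
#'
#' Content edits are only possible while an entity is DRAFT; a FINALIZED
#' entity rejects them with `ImmutableEntity`.
#'
#' @inheritParams define_policy
#' @return The updated entity, invisibly.
#' @export
update_policy <- function(sys, key, label = NULL, properties = NULL, actor = "system") {
  assert_system(sys)
  key <- as_key(key, "policy")
  with_audit(sys, "update_policy", key_string(key), actor, {
    p <- assert_draft(require_entity(sys, key, "policy"), "policy")
    if (!is.null(label)) p$label <- label
    if (!is.null(properties)) {
      validate_properties(properties, strict = TRUE)
      p$properties <- normalize_properties(properties)
    }
    invisible(store_entity(sys, p, "policy"))
  })
}

#' @rdname update_policy
#' @param title,text New module title / descriptive text.
#' @export
update_module <- function(sys, key, title = NULL, text = NULL, properties = NULL,
                          actor = "system") {
  assert_system(sys)
  key <- as_key(key, "module")
  with_audit(sys, "update_module", key_string(key), actor, {
    m <- assert_draft(require_entity(sys, key, "module"), "module")
    if (!is.null(title)) m$title <- title
    if (!is.null(text)) m$text <- text
    if (!is.null(properties)) {
      validate_properties(properties, strict = TRUE)
      m$properties <- normalize_properties(properties)
    }
    invisible(store_entity(sys, m, "module"))
  })
}

#' @rdname update_policy
#' @param header,footer New template header / footer text.
#' @export
update_template <- function(sys, key, header = NULL, footer = NULL,
                            properties = NULL, actor = "system") {
  assert_system(sys)
  key <- as_key(key, "template")
  with_audit(sys, "update_template", key_string(key), actor, {
    tpl <- assert_draft(require_entity(sys, key, "template"), "template")
    if (!is.null(header)) tpl$header <- header
    if (!is.null(footer)) tpl$footer <- footer
    if (!is.null(properties)) {
      validate_properties(properties, strict = TRUE)
      tpl$properties <- normalize_properties(properties)
    }
    invisible(store_entity(sys, tpl, "template"))
  })
}

#' Deprecate a catalogue entity
#'
#' FINALIZED entities are never removed (audit trail); deprecation hides
#' them from default listings.
#'
#' @inheritParams finalize
#' @return The updated entity, invisibly.
#' @export
deprecate_entity <- function(sys, key, kind = c("template", "module", "policy"),
                             actor = "system") {
  assert_system(sys)
  kind <- match.arg(kind)
  key <- as_key(key, kind)
  with_audit(sys, "deprecate_entity", key_string(key), actor, {
    e <- require_entity(sys, key, kind)
    e$deprecated <- TRUE
    invisible(store_entity(sys, e, kind))
  })
}

#' Delete a DRAFT entity
#'
#' Only DRAFT entities can be deleted; once FINALIZED, an entity can only be
#' deprecated.
#'
#' @inheritParams finalize
#' @return `TRUE`, invisibly.
#' @export
delete_draft <- function(sys, key, kind = c("template", "module", "policy"),
                         actor = "system") {
  assert_system(sys)
  kind <- match.arg(kind)
  key <- as_key(key, kind)
  with_audit(sys, "delete_draft", key_string(key), actor, {
    e <- assert_draft(require_entity(sys, key, kind), kind)
    slot <- slot_for(kind)
    sys[[slot]][[key_string(key)]] <- NULL
    invisible(TRUE)
  })
}
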