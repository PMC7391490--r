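# Status engine: resolves the effective consent state of (signer, policy) at
# a given date from the append-only history. Precedence is "latest document
# wins" under a configurable weighting of consent date vs template version;
# expiration is computed at query time from validity specifications collected
# across domain, template, module and policy level (earliest expiry wins);
# raw states aggregate into the three quality classes for boolean queries.

#' Query configuration
#'
#' @param ignore_version_number Match any version of the policy name instead
#'   of the exact versioned key.
#' @param unknown_as_decline Collapse the unknown quality class to
#'   `DECLINED` in aggregation (conservative gate-keeping).
#' @param weighting Precedence among a signer's documents:
#'   `"DATE_THEN_VERSION"` (default; the latest form wins, version breaks
#'   date ties) or `"VERSION_THEN_DATE"` (the newest template version wins,
#'   date breaks version ties).
#' @param at_date Evaluation date; resolution is a pure function of history
#'   and this date, with no hidden clock dependence.
#' @return A list of class `"query_config"`.
#' @examples
#' query_config(unknown_as_decline = TRUE, at_date = "2022-01-01")
#' @export
query_config <- function(ignore_version_number = FALSE, unknown_as_decline = FALSE,
                         weighting = c("DATE_THEN_VERSION", "VERSION_THEN_DATE"),
                         at_date = Sys.Date()) {
  weighting <- match.arg(weighting)
  structure(list(
    ignore_version_number = isTRUE(ignore_version_number),
    unknown_as_decline = isTRUE(unknown_as_decline),
    weighting = weighting,
    at_date = as_consent_date(at_date, "at_date")
  ), class = "query_config")
}

as_query_config <- function(sys, config) {
  if (is.null(config)) {
    return(query_config(ignore_version_number = isTRUE(sys$config$ignore_version_number),
                        unknown_as_decline = isTRUE(sys$config$unknown_as_decline),
                        weighting = sys$config$weighting))
  }
  if (inherits(config, "query_config")) return(config)
  do.call(query_config, as.list(config))
}

# Order documents by the configured weighting; head is the governing one.
# Ties after date, version and timestamp break on document_id so the result
# is fully deterministic.
pick_latest_document <- function(docs, weighting = "DATE_THEN_VERSION") {
  if (length(docs) == 0L) return(NULL)
  dates <- vapply(docs, function(d) as.numeric(d$consent_date), 0)
  vm <- t(vapply(docs, function(d) parse_version(d$template$version), integer(4)))
  ts <- vapply(docs, function(d) as.numeric(d$capture_timestamp), 0)
  ids <- vapply(docs, `[[`, "", "document_id")
  o <- if (weighting == "VERSION_THEN_DATE") {
    order(vm[, 1], vm[, 2], vm[, 3], vm[, 4], dates, ts, xtfrm(ids) * -1,
          decreasing = TRUE, method = "radix")
  } else {
    order(dates, vm[, 1], vm[, 2], vm[, 3], vm[, 4], ts, xtfrm(ids) * -1,
          decreasing = TRUE, method = "radix")
  }
  docs[[o[1]]]
}

#' The governing document of a signer
#'
#' Among the signer's non-invalidated documents in scope with consent date
#' on or before `at_date`, returns the head of the precedence order — the
#' "latest" consent that currently expresses the signer's will.
#'
#' @param sys A [consent_system()].
#' @param signer Signer identifier.
#' @param scope A domain name, or a template name within that domain given
#'   as `c(domain, template_name)`.
#' @param at_date Evaluation date.
#' @param weighting See [query_config()].
#' @return A consent document, or `NULL` when the signer has none.
#' @export
latest_document <- function(sys, signer, scope, at_date = Sys.Date(),
                            weighting = c("DATE_THEN_VERSION", "VERSION_THEN_DATE")) {
  assert_system(sys)
  weighting <- match.arg(weighting)
  at_date <- as_consent_date(at_date, "at_date")
  domain <- scope[[1]]
  docs <- domain_documents(sys, domain, signer)
  if (length(scope) > 1L) {
    docs <- Filter(function(d) d$template$name == scope[[2]], docs)
  }
  docs <- Filter(function(d) is.null(d$invalidation) && d$consent_date <= at_date, docs)
  pick_latest_document(docs, weighting)
}

# ---- expiration -------------------------------------------------------------

collect_validity_specs <- function(sys, doc, policy_key) {
  specs <- list()
  push <- function(props, level) {
    if (!is.null(props[["VALIDITY_FIXED_DATE"]])) {
      specs[[length(specs) + 1L]] <<- list(kind = "FIXED_DATE", level = level,
                                           fixed_date = as_consent_date(props[["VALIDITY_FIXED_DATE"]]))
    }
    if (!is.null(props[["VALIDITY_PERIOD"]])) {
      specs[[length(specs) + 1L]] <<- list(kind = "PERIOD_FROM_CONSENT", level = level,
                                           period = parse_validity_period(props[["VALIDITY_PERIOD"]]))
    }
    if (!is.null(props[["VALIDITY_PERIOD_FROM_BIRTHDATE"]])) {
      specs[[length(specs) + 1L]] <<- list(kind = "PERIOD_FROM_BIRTHDATE", level = level,
                                           period = parse_validity_period(props[["VALIDITY_PERIOD_FROM_BIRTHDATE"]]))
    }
  }
  push(require_domain(sys, doc$template$domain)$properties, "DOMAIN")
  tpl <- lookup_entity(sys, doc$template, "template")
  if (!is.null(tpl)) {
    push(tpl$properties, "TEMPLATE")
    for (a in tpl$module_assignments) {
      m <- lookup_entity(sys, a$module, "module")
      if (!is.null(m) &&
          policy_key$name %in% vapply(m$policies, `[[`, "", "name")) {
        push(m$properties, "MODULE")
      }
    }
  }
  pol <- lookup_entity(sys, policy_key, "policy")
  if (!is.null(pol)) push(pol$properties, "POLICY")
  specs
}

#' Effective expiry date of a policy answer in a document
#'
#' Validity can be limited at domain, template, module and policy level, by
#' a fixed date (e.g. end of the study) or by a period anchored at the
#' consent date or at the signer's birthdate (e.g. a parental consent valid
#' until the 18th birthday). When several specifications apply, the earliest
#' expiry wins — the conservative combination that never extends a
#' permission. The consent is valid on the expiry date itself and expired
#' from the following day.
#'
#' @param sys A [consent_system()].
#' @param document A stored consent document (or its id).
#' @param policy_key The policy whose validity is evaluated.
#' @param signer_birthdate Optional override; defaults to the birthdate on
#'   record for the document's signer.
#' @return A `Date`, or `NULL` when no validity specification applies
#'   (consent is indefinitely valid).
#' @export
effective_expiry <- function(sys, document, policy_key, signer_birthdate = NULL) {
  assert_system(sys)
  if (is.character(document)) document <- get_document(sys, document)
  policy_key <- as_key(policy_key, "policy")
  specs <- collect_validity_specs(sys, document, policy_key)
  if (!length(specs)) return(NULL)
  birthdate <- signer_birthdate %||% get_signer_birthdate(sys, document$signer)
  dates <- lapply(specs, function(sp) {
    switch(sp$kind,
      FIXED_DATE = sp$fixed_date,
      PERIOD_FROM_CONSENT = add_period(document$consent_date, sp$period),
      PERIOD_FROM_BIRTHDATE = {
        if (is.null(birthdate)) {
          stop_consentry("MissingBirthdate",
                         sprintf("birthdate-anchored validity applies but no birthdate is known for %s",
                                 signer_string(document$signer)))
        }
        add_period(as_consent_date(birthdate), sp$period)
      })
  })
  as.Date(min(vapply(dates, as.numeric, 0)), origin = "1970-01-01")
}

# ---- resolution -------------------------------------------------------------

#' @export
print.consent_resolution <- function(x, ...) {
  cat(sprintf("<resolution> %s @ %s\n", key_string(x$policy), iso_date(x$at_date)))
  cat(sprintf("  raw: %-12s quality: %-9s source: %s\n",
              x$raw_state, x$quality, x$source_document %||% "-"))
  if (!is.null(x$expiry_date)) {
    cat(sprintf("  expiry: %s%s\n", iso_date(x$expiry_date),
                if (x$expired) " (expired)" else ""))
  }
  invisible(x)
}

new_resolution <- function(policy_key, signer, config, raw_state, source_document = NULL,
                           expiry_date = NULL, expired = FALSE) {
  structure(list(
    policy = policy_key,
    signer = signer,
    at_date = config$at_date,
    raw_state = raw_state,
    quality = quality_of(raw_state, config$unknown_as_decline),
    source_document = source_document,
    expiry_date = expiry_date,
    expired = expired
  ), class = "consent_resolution")
}

domain_has_policy_name <- function(sys, domain, name) {
  any(vapply(sys$policies, function(p) p$key$domain == domain && p$key$name == name,
             logical(1)))
}

# entry of policy_states matching the query; with ignore_version_number the
# highest answered version of the name wins within one document
matching_entry <- function(doc, policy_key, ignore_version) {
  ks <- key_string(policy_key)
  if (!ignore_version) {
    st <- doc$policy_states[[ks]]
    if (is.null(st)) return(NULL)
    return(list(key = policy_key, state = st))
  }
  keys <- names(doc$policy_states)
  parts <- strsplit(keys, "/", fixed = TRUE)
  hit <- which(vapply(parts, function(p) p[1] == policy_key$domain && p[2] == policy_key$name,
                      logical(1)))
  if (!length(hit)) return(NULL)
  if (length(hit) > 1L) {
    vs <- vapply(hit, function(i) parts[[i]][3], "")
    vm <- t(vapply(vs, parse_version, integer(4)))
    hit <- hit[order(vm[, 1], vm[, 2], vm[, 3], vm[, 4], decreasing = TRUE)[1]]
  }
  p <- parts[[hit]]
  list(key = consent_key(p[1], p[2], p[3], "policy"),
       state = doc$policy_states[[keys[hit]]])
}

#' Resolve the effective consent status of a policy
#'
#' Gathers the signer's documents that answer the policy (the exact
#' versioned key, or any version of the policy name under
#' `ignore_version_number`), picks the governing document by the configured
#' precedence, and reports its stored raw state — replaced by `EXPIRED`
#' when the state was `ACCEPTED` and the evaluation date lies after the
#' effective expiry. A signer never asked resolves as raw `UNKNOWN` with no
#' source document: participants consented under an older template version
#' were simply not asked policies added later. When only invalidated
#' documents answer the policy, the resolution is `INVALIDATED`.
#'
#' @param sys A [consent_system()].
#' @param signer Signer identifier.
#' @param policy_key Policy key (object or `"domain/name/version"` string).
#' @param config A [query_config()]; defaults derive from the store
#'   configuration with `at_date = Sys.Date()`.
#' @return A `"consent_resolution"`: raw state, quality class, source
#'   document id, expiry date and expired flag.
#' @export
resolve_policy_status <- function(sys, signer, policy_key, config = NULL) {
  assert_system(sys)
  policy_key <- as_key(policy_key, "policy")
  config <- as_query_config(sys, config)
  signer <- as_signer(signer)
  if (!domain_has_policy_name(sys, policy_key$domain, policy_key$name)) {
    stop_consentry("UnknownPolicy",
                   sprintf("no policy named '%s' in domain '%s'",
                           policy_key$name, policy_key$domain))
  }
  docs <- domain_documents(sys, policy_key$domain, signer)
  docs <- Filter(function(d) d$consent_date <= config$at_date, docs)
  answering <- Filter(function(d) !is.null(matching_entry(d, policy_key, config$ignore_version_number)),
                      docs)
  valid <- Filter(function(d) is.null(d$invalidation), answering)
  if (length(valid)) {
    doc <- pick_latest_document(valid, config$weighting)
    entry <- matching_entry(doc, policy_key, config$ignore_version_number)
    expiry <- effective_expiry(sys, doc, entry$key)
    expired <- identical(entry$state, "ACCEPTED") && !is.null(expiry) &&
      config$at_date > expiry
    raw <- if (expired) "EXPIRED" else entry$state
    return(new_resolution(policy_key, signer, config, raw,
                          source_document = doc$document_id,
                          expiry_date = expiry, expired = expired))
  }
  if (length(answering)) {  # only invalidated documents ever answered it
    doc <- pick_latest_document(answering, config$weighting)
    return(new_resolution(policy_key, signer, config, "INVALIDATED",
                          source_document = doc$document_id))
  }
  new_resolution(policy_key, signer, config, "UNKNOWN")
}

#' Boolean consent check
#'
#' `TRUE` exactly when the resolved quality class is `ACCEPTED`: an
#' unexpired, unwithdrawn, uninvalidated express consent.
#'
#' @inheritParams resolve_policy_status
#' @return Logical scalar.
#' @examples
#' \dontrun{is_consented(sys, "pseudonym:P-0001", "study/data_collection/1.0")}
#' @export
is_consented <- function(sys, signer, policy_key, config = NULL) {
  identical(resolve_policy_status(sys, signer, policy_key, config)$quality, "ACCEPTED")
}
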