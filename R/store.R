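# Append-only consent document store. A document records one capture event:
# an initial consent (digitized paper form or fully electronic), or a
# withdrawal that re-states the signer's complete current will. Documents are
# never edited or deleted; invalidations and scan uploads are strictly
# additive annotations.

.SCAN_CONTENT_TYPES <- c("application/pdf", "image/jpeg")

new_document_id <- function(sys) {
  sys$doc_counter <- sys$doc_counter + 1L
  sprintf("doc-%06d", sys$doc_counter)
}

default_timestamp <- function(sys, consent_date) {
  # deterministic, monotone per store; used only for tie-breaking
  as.POSIXct(as.numeric(as.POSIXct(consent_date, tz = "UTC")) + sys$doc_counter,
             origin = "1970-01-01", tz = "UTC")
}

#' @export
print.consent_document <- function(x, ...) {
  cat(sprintf("<consent_document %s>\n", x$document_id))
  cat(sprintf("  signer:   %s\n", signer_string(x$signer)))
  cat(sprintf("  template: %s (%s)\n", key_string(x$template), x$capture_mode))
  cat(sprintf("  date:     %s%s\n", iso_date(x$consent_date),
              if (!is.null(x$withdrawal_of)) sprintf("  [withdrawal of %s]", x$withdrawal_of) else ""))
  if (!is.null(x$invalidation)) {
    cat(sprintf("  INVALIDATED %s: %s\n", iso_date(x$invalidation$date), x$invalidation$reason))
  }
  st <- unlist(x$policy_states)
  for (k in names(st)) cat(sprintf("    %-40s %s\n", k, st[[k]]))
  if (length(x$scans)) cat(sprintf("  scans: %d\n", length(x$scans)))
  invisible(x)
}

validate_signer <- function(sys, signer, domain) {
  signer <- as_signer(signer)
  d <- require_domain(sys, domain)
  if (!signer$id_type %in% d$signer_id_types) {
    stop_consentry("UnknownSignerIdType",
                   sprintf("id type '%s' is not registered for domain '%s'",
                           signer$id_type, domain))
  }
  signer
}

coerce_free_text <- function(def, value) {
  fail <- function(why) {
    stop_consentry("FreeTextValidation",
                   sprintf("field '%s' (%s): %s", def$name, def$value_type, why))
  }
  if (is.null(value) || (length(value) != 1L)) fail("a single value is required")
  switch(def$value_type,
    STRING = as.character(value),
    DATE = tryCatch(as_consent_date(value, def$name),
                    consentry_error = function(e) fail("not an ISO date")),
    BOOLEAN = {
      v <- tolower(as.character(value))
      if (isTRUE(value) || v %in% c("true", "1")) TRUE
      else if (identical(value, FALSE) || v %in% c("false", "0")) FALSE
      else fail("not a boolean")
    },
    INTEGER = {
      if (is.numeric(value) && value == as.integer(value)) as.integer(value)
      else if (grepl("^-?[0-9]+$", as.character(value))) as.integer(value)
      else fail(sprintf("'%s' is not an integer", value))
    },
    DOUBLE = {
      v <- suppressWarnings(as.numeric(value))
      if (is.na(v)) fail(sprintf("'%s' is not a number", value)) else v
    }
  )
}

validate_free_text_values <- function(defs, values) {
  values <- as.list(values)
  known <- vapply(defs, `[[`, "", "name")
  extra <- setdiff(names(values), known)
  if (length(extra)) {
    stop_consentry("FreeTextValidation",
                   sprintf("field '%s' is not defined by the template", extra[1]))
  }
  out <- list()
  for (def in defs) {
    v <- values[[def$name]]
    if (is.null(v)) {
      if (def$required) {
        stop_consentry("FreeTextValidation",
                       sprintf("required field '%s' is missing", def$name))
      }
      next
    }
    out[[def$name]] <- coerce_free_text(def, v)
  }
  out
}

validate_scan_payload <- function(sys, domain, blob, content_type) {
  if (identical(content_type, "image/jpg")) content_type <- "image/jpeg"
  if (!content_type %in% .SCAN_CONTENT_TYPES) {
    stop_consentry("UnsupportedContentType",
                   sprintf("'%s' not supported (PDF or JPEG only)", content_type))
  }
  if (!is.raw(blob)) stop_consentry("UnsupportedContentType", "scan blob must be raw bytes")
  lim <- require_domain(sys, domain)$properties[["SCAN_SIZE_LIMIT"]]
  if (!is.null(lim) && length(blob) > parse_property_int(lim)) {
    stop_consentry("ScanTooLarge",
                   sprintf("scan of %d bytes exceeds SCAN_SIZE_LIMIT=%s", length(blob), lim))
  }
  list(blob = blob, content_type = content_type)
}

domain_documents <- function(sys, domain, signer = NULL) {
  docs <- Filter(function(d) d$template$domain == domain, sys$documents)
  if (!is.null(signer)) {
    ss <- signer_string(as_signer(signer))
    docs <- Filter(function(d) signer_string(d$signer) == ss, docs)
  }
  unname(docs)
}

# latest effective raw state the signer has on record for a policy name,
# across non-invalidated documents (used by the permanent-withdrawal guard)
prior_withdrawn_names <- function(sys, domain, signer) {
  docs <- Filter(function(d) is.null(d$invalidation),
                 domain_documents(sys, domain, signer))
  if (!length(docs)) return(character())
  names_of <- function(ks) vapply(strsplit(ks, "/", fixed = TRUE), `[[`, "", 2)
  state_by_name <- list()  # latest state per policy name, in document order
  for (d in docs[order(vapply(docs, function(x) as.numeric(x$capture_timestamp), 0))]) {
    st <- unlist(d$policy_states)
    nm <- names_of(names(st))
    for (i in seq_along(st)) state_by_name[[nm[i]]] <- st[[i]]
  }
  names(Filter(function(s) s == "WITHDRAWN", state_by_name))
}

#' Record a consent document
#'
#' Captures one filled-in consent form for a signer. Decisions are given per
#' module and fanned out to each of the module's policies; individual
#' policies may be overridden (e.g. one declined question inside an accepted
#' module). The referenced template is finalized automatically on first use,
#' so a form can never change once a participant has signed it.
#'
#' A decision for a module flagged mandatory must be `ACCEPTED`; otherwise
#' the capture is rejected with `MandatoryModuleNotAccepted` (or, when the
#' store is configured with `allow_incomplete_mandatory`, archived as an
#' already-invalidated document that never governs resolution).
#'
#' @param sys A [consent_system()].
#' @param signer A [signer_id()] or `"id_type:value"` string.
#' @param template_key Template key (object or `"domain/name/version"`).
#' @param consent_date Calendar date on the form (day precision).
#' @param decisions Named vector/list `module name -> state` with states from
#'   `ACCEPTED`, `DECLINED`, `UNKNOWN`, `NOT_ASKED`, `NOT_CHOSEN`, `REFUSED`;
#'   or the single string `"REFUSED"` to record a whole-document refusal.
#' @param free_text Named list of free-text values, validated against the
#'   template's field definitions.
#' @param capture_mode `"PAPER_DIGITIZED"` or `"ELECTRONIC"`.
#' @param scans Optional list of `list(blob = <raw>, content_type =)` scan
#'   attachments captured together with the document.
#' @param policy_overrides Named vector/list `policy key string -> state`
#'   overriding the module-level decision for single policies.
#' @param capture_timestamp Optional explicit timestamp (tie-breaking only);
#'   defaults to a deterministic per-store sequence.
#' @param actor Audit actor.
#' @return The stored document, invisibly.
#' @export
record_consent <- function(sys, signer, template_key, consent_date, decisions,
                           free_text = list(),
                           capture_mode = c("PAPER_DIGITIZED", "ELECTRONIC"),
                           scans = list(), policy_overrides = list(),
                           capture_timestamp = NULL, actor = "system") {
  assert_system(sys)
  capture_mode <- match.arg(capture_mode)
  tkey <- as_key(template_key, "template")
  with_audit(sys, "record_consent", signer_string(as_signer(signer)), actor, {
    tpl <- require_entity(sys, tkey, "template")
    signer <- validate_signer(sys, signer, tkey$domain)
    consent_date <- as_consent_date(consent_date, "consent_date")

    decisions <- as.list(decisions)
    if (length(decisions) == 1L && is.null(names(decisions)) &&
        identical(decisions[[1]], "REFUSED")) {
      decisions <- stats::setNames(
        as.list(rep("REFUSED", length(tpl$module_assignments))),
        vapply(tpl$module_assignments, function(a) a$module$name, ""))
    }
    mod_names <- vapply(tpl$module_assignments, function(a) a$module$name, "")
    extra <- setdiff(names(decisions), mod_names)
    if (length(extra)) {
      stop_consentry("UnknownModule",
                     sprintf("template has no module named '%s'", extra[1]))
    }
    missing <- setdiff(mod_names, names(decisions))
    if (length(missing)) {
      stop_consentry("MissingModuleDecision",
                     sprintf("no decision given for module '%s'", missing[1]))
    }
    for (s in unlist(decisions)) {
      if (!s %in% .CAPTURE_STATES) {
        stop_consentry("UnknownState",
                       sprintf("'%s' is not a capturable state", s))
      }
    }
    overrides <- as.list(policy_overrides)
    for (s in unlist(overrides)) {
      if (!s %in% .CAPTURE_STATES) {
        stop_consentry("UnknownState", sprintf("'%s' is not a capturable state", s))
      }
    }

    # fan module decisions out to the module's policies
    policy_states <- list()
    for (a in tpl$module_assignments) {
      m <- require_entity(sys, a$module, "module")
      decision <- decisions[[a$module$name]]
      if (a$mandatory && !identical(decision, "ACCEPTED")) {
        if (!isTRUE(sys$config$allow_incomplete_mandatory)) {
          stop_consentry("MandatoryModuleNotAccepted",
                         sprintf("mandatory module '%s' was not accepted", a$module$name))
        }
      }
      for (p in m$policies) {
        ks <- key_string(p)
        policy_states[[ks]] <- overrides[[ks]] %||% decision
      }
    }
    bad_override <- setdiff(names(overrides), names(policy_states))
    if (length(bad_override)) {
      stop_consentry("UnknownPolicy",
                     sprintf("override names policy '%s' outside the template", bad_override[1]))
    }

    # permanent-withdrawal guard: a withdrawn will is final for the domain
    perm <- property_flag(require_domain(sys, tkey$domain)$properties, "PERMANENT_WITHDRAWAL") ||
      property_flag(tpl$properties, "PERMANENT_WITHDRAWAL")
    if (perm) {
      withdrawn <- prior_withdrawn_names(sys, tkey$domain, signer)
      touched <- vapply(strsplit(names(policy_states), "/", fixed = TRUE), `[[`, "", 2)
      hit <- intersect(touched, withdrawn)
      if (length(hit)) {
        stop_consentry("PermanentWithdrawalBlock",
                       sprintf("policy '%s' was permanently withdrawn by this signer", hit[1]))
      }
    }

    free_text_values <- validate_free_text_values(tpl$free_text_defs, free_text)

    mandatory_ok <- all(vapply(tpl$module_assignments, function(a) {
      !a$mandatory || identical(decisions[[a$module$name]], "ACCEPTED")
    }, logical(1)))

    ts <- capture_timestamp %||% default_timestamp(sys, consent_date)
    scan_list <- lapply(scans, function(s) {
      v <- validate_scan_payload(sys, tkey$domain, s$blob, s$content_type)
      list(blob = v$blob, content_type = v$content_type, uploaded_at = ts)
    })

    finalize_core(sys, tkey, "template")  # auto-finalize on first use

    doc <- structure(list(
      document_id = new_document_id(sys),
      signer = signer,
      template = tkey,
      consent_date = consent_date,
      capture_timestamp = ts,
      capture_mode = capture_mode,
      policy_states = policy_states,
      free_text_values = free_text_values,
      scans = scan_list,
      invalidation = if (mandatory_ok) NULL else
        list(reason = "mandatory module not accepted", date = consent_date),
      withdrawal_of = NULL
    ), class = "consent_document")
    sys$documents[[doc$document_id]] <- doc
    invisible(doc)
  })
}

expand_withdrawal_scope <- function(sys, domain, scope, answered) {
  answered_names <- vapply(strsplit(answered, "/", fixed = TRUE), `[[`, "", 2)
  out <- character()
  for (el in scope) {
    ks <- key_string(el)
    if (ks %in% answered) { out <- c(out, ks); next }
    mod <- sys$modules[[ks]]
    if (!is.null(mod) && mod$key$domain == domain) {
      hits <- intersect(vapply(mod$policies, key_string, ""), answered)
      if (!length(hits)) {
        stop_consentry("UnknownPolicyInScope",
                       sprintf("module '%s' contains no policy this signer was asked", ks))
      }
      out <- c(out, hits)
      next
    }
    # a bare policy name withdraws every answered version of that policy
    if (!grepl("/", ks) && ks %in% answered_names) {
      out <- c(out, answered[answered_names == ks])
      next
    }
    stop_consentry("UnknownPolicyInScope",
                   sprintf("'%s' names no policy this signer was asked", ks))
  }
  unique(out)
}

#' Record a (partial or full) withdrawal
#'
#' Withdrawal never edits history: a new versioned document is appended that
#' re-states the signer's complete current will. Policies in scope get raw
#' state `WITHDRAWN`; every other policy the signer had previously answered
#' in the domain carries its latest effective raw state forward, so the
#' newest document alone suffices to resolve any policy. With a partial
#' scope, analyses based on the remaining consented policies can continue.
#'
#' @param sys A [consent_system()].
#' @param signer Signer identifier.
#' @param domain Domain name.
#' @param scope `"FULL"`, or a list of policy keys, module keys, or bare
#'   policy names (a bare name withdraws every answered version).
#' @param withdrawal_date Calendar date of the withdrawal.
#' @param capture_mode How the withdrawal was captured.
#' @param capture_timestamp Optional explicit timestamp.
#' @param actor Audit actor.
#' @return The stored withdrawal document, invisibly.
#' @export
record_withdrawal <- function(sys, signer, domain, scope = "FULL",
                              withdrawal_date,
                              capture_mode = c("ELECTRONIC", "PAPER_DIGITIZED"),
                              capture_timestamp = NULL, actor = "system") {
  assert_system(sys)
  capture_mode <- match.arg(capture_mode)
  with_audit(sys, "record_withdrawal", signer_string(as_signer(signer)), actor, {
    require_domain(sys, domain)
    signer <- validate_signer(sys, signer, domain)
    withdrawal_date <- as_consent_date(withdrawal_date, "withdrawal_date")
    docs <- Filter(function(d) is.null(d$invalidation),
                   domain_documents(sys, domain, signer))
    docs <- Filter(function(d) d$consent_date <= withdrawal_date, docs)
    if (!length(docs)) {
      stop_consentry("NoPriorConsent",
                     sprintf("signer %s has no prior consent in domain '%s'",
                             signer_string(signer), domain))
    }
    governing <- pick_latest_document(docs, sys$config$weighting)

    # carry forward the latest effective raw state of every answered policy
    answered <- unique(unlist(lapply(docs, function(d) names(d$policy_states))))
    carried <- stats::setNames(vapply(answered, function(ks) {
      cand <- Filter(function(d) !is.null(d$policy_states[[ks]]), docs)
      unlist(pick_latest_document(cand, sys$config$weighting)$policy_states[[ks]])
    }, ""), answered)

    in_scope <- if (identical(scope, "FULL")) answered
                else expand_withdrawal_scope(sys, domain, scope, answered)
    carried[in_scope] <- "WITHDRAWN"

    ts <- capture_timestamp %||% default_timestamp(sys, withdrawal_date)
    doc <- structure(list(
      document_id = new_document_id(sys),
      signer = signer,
      template = governing$template,
      consent_date = withdrawal_date,
      capture_timestamp = ts,
      capture_mode = capture_mode,
      policy_states = as.list(carried),
      free_text_values = list(),
      scans = list(),
      invalidation = NULL,
      withdrawal_of = governing$document_id
    ), class = "consent_document")
    sys$documents[[doc$document_id]] <- doc
    invisible(doc)
  })
}

#' Invalidate a stored document
#'
#' Marks a document invalid (participant excluded retrospectively, or the
#' capture failed for formal/technical reasons). The document itself is kept
#' — the annotation is additive — but resolution treats all its policy
#' states as `INVALIDATED` and it never governs when a valid document
#' exists.
#'
#' @param sys A [consent_system()].
#' @param document_id Document identifier.
#' @param reason Free-text reason.
#' @param date Invalidation date.
#' @param actor Audit actor.
#' @return The annotated document, invisibly.
#' @export
invalidate_document <- function(sys, document_id, reason, date, actor = "system") {
  assert_system(sys)
  with_audit(sys, "invalidate_document", document_id, actor, {
    doc <- sys$documents[[document_id]]
    if (is.null(doc)) stop_consentry("UnknownDocument", sprintf("no document '%s'", document_id))
    if (!is.null(doc$invalidation)) {
      stop_consentry("AlreadyInvalidated", sprintf("document '%s' is already invalidated", document_id))
    }
    doc$invalidation <- list(reason = as.character(reason),
                             date = as_consent_date(date, "invalidation date"))
    sys$documents[[document_id]] <- doc
    invisible(doc)
  })
}

#' Attach a scan to a document
#'
#' Paper-based workflows digitize the signed form asynchronously: the
#' document can be captured first and the scan (PDF or JPEG) uploaded later.
#' Multiple scans per document are kept in upload order.
#'
#' @param sys A [consent_system()].
#' @param document_id Document identifier.
#' @param blob Raw vector with the file content, or a file path.
#' @param content_type `"application/pdf"` or `"image/jpeg"`.
#' @param uploaded_at Upload timestamp.
#' @param actor Audit actor.
#' @return The attachment record, invisibly.
#' @export
attach_scan <- function(sys, document_id, blob, content_type,
                        uploaded_at = Sys.time(), actor = "system") {
  assert_system(sys)
  with_audit(sys, "attach_scan", document_id, actor, {
    doc <- sys$documents[[document_id]]
    if (is.null(doc)) stop_consentry("UnknownDocument", sprintf("no document '%s'", document_id))
    if (is.character(blob)) blob <- readBin(blob, "raw", n = file.size(blob))
    v <- validate_scan_payload(sys, doc$template$domain, blob, content_type)
    att <- list(blob = v$blob, content_type = v$content_type, uploaded_at = uploaded_at)
    doc$scans[[length(doc$scans) + 1L]] <- att
    sys$documents[[document_id]] <- doc
    invisible(att)
  })
}

#' Fetch a stored document
#' @inheritParams invalidate_document
#' @return The document.
#' @export
get_document <- function(sys, document_id) {
  assert_system(sys)
  doc <- sys$documents[[document_id]]
  if (is.null(doc)) stop_consentry("UnknownDocument", sprintf("no document '%s'", document_id))
  doc
}

#' List a document's scan attachments
#' @inheritParams invalidate_document
#' @return Data frame with `content_type`, `size_bytes`, `uploaded_at`, in
#'   upload order.
#' @export
list_scans <- function(sys, document_id) {
  doc <- get_document(sys, document_id)
  data.frame(
    content_type = vapply(doc$scans, `[[`, "", "content_type"),
    size_bytes = vapply(doc$scans, function(s) length(s$blob), integer(1)),
    uploaded_at = as.POSIXct(vapply(doc$scans, function(s) as.numeric(s$uploaded_at), 0),
                             origin = "1970-01-01", tz = "UTC"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Record a signer's birthdate
#'
#' Needed only when a birthdate-anchored validity period applies (e.g. a
#' parental consent valid until the participant's 18th birthday).
#'
#' @param sys A [consent_system()].
#' @param signer Signer identifier.
#' @param birthdate Calendar date.
#' @param actor Audit actor.
#' @return The birthdate, invisibly.
#' @export
set_signer_birthdate <- function(sys, signer, birthdate, actor = "system") {
  assert_system(sys)
  signer <- as_signer(signer)
  with_audit(sys, "set_signer_birthdate", signer_string(signer), actor, {
    bd <- as_consent_date(birthdate, "birthdate")
    sys$birthdates[[signer_string(signer)]] <- bd
    invisible(bd)
  })
}

#' @rdname set_signer_birthdate
#' @return `get_signer_birthdate` returns the `Date` or `NULL`.
#' @export
get_signer_birthdate <- function(sys, signer) {
  assert_system(sys)
  sys$birthdates[[signer_string(as_signer(signer))]]
}

#' List signers known to a domain
#'
#' @param sys A [consent_system()].
#' @param domain Domain name.
#' @return Data frame with `id_type` and `value`, sorted, one row per
#'   distinct signer appearing in the domain's document history.
#' @export
list_signers <- function(sys, domain) {
  assert_system(sys)
  require_domain(sys, domain)
  docs <- domain_documents(sys, domain)
  ss <- sort(unique(vapply(docs, function(d) signer_string(d$signer), "")))
  parts <- strsplit(ss, ":", fixed = TRUE)
  data.frame(
    id_type = vapply(parts, `[[`, "", 1),
    value = vapply(parts, `[[`, "", 2),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
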