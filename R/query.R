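# Study-management queries and consented-case exports built on the status
# engine. All result tables are deterministically sorted (signer, then
# policy key) so repeated runs over an unchanged store are identical.

resolution_row <- function(signer, res) {
  data.frame(
    signer_id_type = signer$id_type,
    signer_id = signer$value,
    policy_domain = res$policy$domain,
    policy_name = res$policy$name,
    policy_version = res$policy$version,
    raw_state = res$raw_state,
    quality = res$quality,
    document_id = res$source_document %||% NA_character_,
    consent_date = NA_character_,
    expiry_date = iso_date(res$expiry_date),
    stringsAsFactors = FALSE
  )
}

empty_result <- function() {
  data.frame(signer_id_type = character(), signer_id = character(),
             policy_domain = character(), policy_name = character(),
             policy_version = character(), raw_state = character(),
             quality = character(), document_id = character(),
             consent_date = character(), expiry_date = character(),
             stringsAsFactors = FALSE)
}

sort_result <- function(df) {
  if (nrow(df) == 0L) return(df)
  o <- order(df$signer_id_type, df$signer_id, df$policy_domain, df$policy_name,
             df$policy_version, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

fill_consent_date <- function(sys, df) {
  if (nrow(df)) {
    df$consent_date <- vapply(df$document_id, function(id) {
      if (is.na(id)) NA_character_ else iso_date(sys$documents[[id]]$consent_date)
    }, "")
  }
  df
}

#' Participants who consented to a policy
#'
#' One row per signer whose resolved quality class is `ACCEPTED` at the
#' evaluation date — the data-trustee query behind "who may we include".
#' Withdrawn, invalidated and expired consents are excluded by
#' construction.
#'
#' @param sys A [consent_system()].
#' @param policy_key Policy key.
#' @param config A [query_config()].
#' @return Sorted data frame with signer, policy, raw state, quality,
#'   source document, consent and expiry dates.
#' @export
participants_consented_to <- function(sys, policy_key, config = NULL) {
  assert_system(sys)
  policy_key <- as_key(policy_key, "policy")
  config <- as_query_config(sys, config)
  if (!domain_has_policy_name(sys, policy_key$domain, policy_key$name)) {
    stop_consentry("UnknownPolicy",
                   sprintf("no policy named '%s' in domain '%s'",
                           policy_key$name, policy_key$domain))
  }
  signers <- list_signers(sys, policy_key$domain)
  rows <- list()
  for (i in seq_len(nrow(signers))) {
    s <- signer_id(signers$id_type[i], signers$value[i])
    res <- resolve_policy_status(sys, s, policy_key, config)
    if (identical(res$quality, "ACCEPTED")) rows[[length(rows) + 1L]] <- resolution_row(s, res)
  }
  df <- if (length(rows)) do.call(rbind, rows) else empty_result()
  sort_result(fill_consent_date(sys, df))
}

#' Policies a participant has consented to
#'
#' @param sys A [consent_system()].
#' @param signer Signer identifier.
#' @param domain Domain name.
#' @param config A [query_config()].
#' @return Sorted data frame, one row per registered policy version whose
#'   resolved quality is `ACCEPTED` for this signer.
#' @export
policies_consented_by <- function(sys, signer, domain, config = NULL) {
  assert_system(sys)
  require_domain(sys, domain)
  config <- as_query_config(sys, config)
  signer <- as_signer(signer)
  rows <- list()
  for (p in list_policies(sys, domain, include_deprecated = TRUE)) {
    res <- resolve_policy_status(sys, signer, p$key, config)
    if (identical(res$quality, "ACCEPTED")) {
      rows[[length(rows) + 1L]] <- resolution_row(signer, res)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else empty_result()
  sort_result(fill_consent_date(sys, df))
}

#' Documents whose paper form still lacks a scan
#'
#' Digitized paper documents without any scan attachment; fully electronic
#' documents are included only when the domain property `MANDATORY_SCANS`
#' requires a scan for every document.
#'
#' @param sys A [consent_system()].
#' @param domain Domain name.
#' @return List of documents in chronological order.
#' @export
documents_missing_scan <- function(sys, domain) {
  assert_system(sys)
  d <- require_domain(sys, domain)
  mandatory <- property_flag(d$properties, "MANDATORY_SCANS")
  docs <- Filter(function(doc) {
    length(doc$scans) == 0L &&
      (doc$capture_mode == "PAPER_DIGITIZED" || mandatory)
  }, domain_documents(sys, domain))
  order_documents(docs)
}

order_documents <- function(docs) {
  if (length(docs) <= 1L) return(docs)
  o <- order(vapply(docs, function(d) as.numeric(d$consent_date), 0),
             vapply(docs, function(d) as.numeric(d$capture_timestamp), 0),
             vapply(docs, `[[`, "", "document_id"),
             method = "radix")
  docs[o]
}

#' Full document history of a participant
#'
#' Everything on file, including withdrawals and invalidated documents, in
#' chronological order — the complete audit view of one participant's
#' consent life cycle.
#'
#' @inheritParams policies_consented_by
#' @return List of documents.
#' @export
documents_of <- function(sys, signer, domain) {
  assert_system(sys)
  require_domain(sys, domain)
  order_documents(domain_documents(sys, domain, signer))
}

#' The participant's current consent form
#'
#' @inheritParams policies_consented_by
#' @return The governing document per [latest_document()], or `NULL`.
#' @export
current_document_of <- function(sys, signer, domain, config = NULL) {
  assert_system(sys)
  config <- as_query_config(sys, config)
  latest_document(sys, signer, domain, at_date = config$at_date,
                  weighting = config$weighting)
}

#' Export consented cases
#'
#' The trusted-third-party deliverable: one row per (signer, policy) with
#' quality `ACCEPTED`, e.g. the list of pseudonyms with valid consents that
#' a data-management unit may process. Output is byte-stable for a fixed
#' store and configuration. Scan blobs are never exported and free-text
#' values only on request (data minimisation).
#'
#' @param sys A [consent_system()].
#' @param domain Domain name.
#' @param policy_keys List of policy keys to export (default: every policy
#'   of the domain).
#' @param config A [query_config()].
#' @param format `"csv"` (UTF-8, RFC-4180 quoting, ISO-8601 dates, LF line
#'   endings) or `"json"`.
#' @param path Optional output file.
#' @param include_free_text Add one column per free-text field of the source
#'   document's template.
#' @return The export artifact as a single string (also written to `path`
#'   when given, invisibly then).
#' @export
export_consented <- function(sys, domain, policy_keys = NULL, config = NULL,
                             format = c("csv", "json"), path = NULL,
                             include_free_text = FALSE) {
  assert_system(sys)
  format <- match.arg(format)
  require_domain(sys, domain)
  config <- as_query_config(sys, config)
  if (is.null(policy_keys)) {
    policy_keys <- lapply(list_policies(sys, domain, include_deprecated = TRUE), `[[`, "key")
  }
  parts <- lapply(policy_keys, function(k) participants_consented_to(sys, k, config))
  df <- if (length(parts)) do.call(rbind, parts) else empty_result()
  df <- sort_result(df)
  out <- df[, c("signer_id_type", "signer_id", "policy_domain", "policy_name",
                "policy_version", "quality", "consent_date", "expiry_date")]
  if (include_free_text && nrow(out)) {
    fts <- vapply(seq_len(nrow(out)), function(i) {
      doc <- sys$documents[[df$document_id[i]]]
      if (is.null(doc) || !length(doc$free_text_values)) return("")
      vals <- vapply(doc$free_text_values, function(v) {
        if (inherits(v, "Date")) iso_date(v) else as.character(v)
      }, "")
      paste(sprintf("%s=%s", names(vals), vals), collapse = ";")
    }, "")
    out$free_text <- fts
  }
  artifact <- if (format == "csv") {
    con <- textConnection("csv_lines", "w", local = TRUE)
    utils::write.csv(out, con, row.names = FALSE, na = "")
    close(con)
    paste0(paste(csv_lines, collapse = "\n"), "\n")
  } else {
    paste0(jsonlite::toJSON(out, dataframe = "rows", na = "null", auto_unbox = FALSE,
                            digits = NA, pretty = TRUE), "\n")
  }
  if (!is.null(path)) {
    writeChar(artifact, path, eos = NULL, useBytes = TRUE)
    return(invisible(artifact))
  }
  artifact
}
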