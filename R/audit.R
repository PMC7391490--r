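# Append-only audit log. Every public mutating operation writes exactly one
# record, for successes and for rejected attempts alike, so the trail shows
# who tried what and with which outcome.

#' Append an audit record
#'
#' Mutating operations call this automatically; it is exported so service
#' frontends can log their own composite operations.
#'
#' @param sys A [consent_system()].
#' @param operation Operation name.
#' @param entity_ref Identifier of the affected entity (key string, document
#'   id, signer string, ...).
#' @param outcome `"SUCCESS"` or the error name of a rejected attempt.
#' @param actor Caller-supplied actor string (the engine performs no
#'   authentication by design; identity management is out of scope).
#' @param timestamp Record timestamp.
#' @return The record, invisibly.
#' @export
audit_append <- function(sys, operation, entity_ref, outcome = "SUCCESS",
                         actor = "system", timestamp = Sys.time()) {
  assert_system(sys)
  rec <- list(
    seq = length(sys$audit) + 1L,
    timestamp = timestamp,
    actor = as.character(actor),
    operation = as.character(operation),
    entity_ref = as.character(entity_ref),
    outcome = as.character(outcome)
  )
  sys$audit[[length(sys$audit) + 1L]] <- rec
  invisible(rec)
}

#' List audit records
#'
#' @param sys A [consent_system()].
#' @param operation Optional operation-name filter.
#' @param entity Optional entity-reference filter (exact match).
#' @param from,to Optional timestamp range (inclusive).
#' @return Data frame with one row per record, in append order: `seq`,
#'   `timestamp`, `actor`, `operation`, `entity_ref`, `outcome`.
#' @export
audit_list <- function(sys, operation = NULL, entity = NULL, from = NULL, to = NULL) {
  assert_system(sys)
  recs <- sys$audit
  keep <- vapply(recs, function(r) {
    (is.null(operation) || r$operation == operation) &&
      (is.null(entity) || r$entity_ref == entity) &&
      (is.null(from) || r$timestamp >= from) &&
      (is.null(to) || r$timestamp <= to)
  }, logical(1))
  recs <- recs[keep]
  data.frame(
    seq = vapply(recs, `[[`, integer(1), "seq"),
    timestamp = as.POSIXct(vapply(recs, function(r) as.numeric(r$timestamp), numeric(1)),
                           origin = "1970-01-01", tz = "UTC"),
    actor = vapply(recs, `[[`, character(1), "actor"),
    operation = vapply(recs, `[[`, character(1), "operation"),
    entity_ref = vapply(recs, `[[`, character(1), "entity_ref"),
    outcome = vapply(recs, `[[`, character(1), "outcome"),
    stringsAsFactors = FALSE
  )
}

# Run a mutating core expression under audit: one record on success, one
# (with the error name as outcome) on an engine rejection, then re-raise.
with_audit <- function(sys, operation, entity_ref, actor, expr) {
  tryCatch({
    res <- force(expr)
    audit_append(sys, operation, entity_ref, "SUCCESS", actor)
    invisible(res)
  }, consentry_error = function(e) {
    audit_append(sys, operation, entity_ref, class(e)[1], actor)
    stop(e)
  })
}
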