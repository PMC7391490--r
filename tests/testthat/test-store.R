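# Capture, withdrawal, invalidation and scan workflows of the append-only
# document store.

test_that("record_consent stores an individual participant document", {
  sys <- base_system()
  doc <- accept_all(sys, "pseudonym:P1")
  expect_s3_class(doc, "consent_document")
  # fan-out: one raw state per distinct policy across the template's modules
  expect_length(doc$policy_states, 3L)
  expect_true(all(unlist(doc$policy_states) == "ACCEPTED"))
  expect_identical(doc$capture_mode, "PAPER_DIGITIZED")
  # auto-finalize on first use: the signed form is now immutable
  expect_true(is_finalized(sys, "study/consent/1.0", "template"))
  expect_error(update_template(sys, "study/consent/1.0", header = "x"),
               class = "ImmutableEntity")
  # unknown signer id types are rejected at capture
  expect_error(accept_all(sys, "case_number:77"), class = "UnknownSignerIdType")
})

test_that("a participant can decline an optional module", {
  sys <- base_system()
  doc <- record_consent(sys, "pseudonym:P1", "study/consent/1.0", "2020-01-01",
                        list(core = "ACCEPTED", bio = "DECLINED"))
  expect_identical(doc$policy_states[["study/dna/1.0"]], "DECLINED")
  expect_identical(doc$policy_states[["study/collect/1.0"]], "ACCEPTED")
  # per-policy override inside an accepted module
  doc2 <- record_consent(sys, "pseudonym:P2", "study/consent/1.0", "2020-01-01",
                         list(core = "ACCEPTED", bio = "ACCEPTED"),
                         policy_overrides = list("study/store/1.0" = "DECLINED"))
  expect_identical(doc2$policy_states[["study/store/1.0"]], "DECLINED")
  expect_identical(doc2$policy_states[["study/collect/1.0"]], "ACCEPTED")
  # whole-document refusal fans REFUSED to every policy
  doc3 <- record_consent(sys, "pseudonym:P3", "study/consent/1.0", "2020-01-01", "REFUSED")
  expect_true(all(unlist(doc3$policy_states) == "REFUSED"))
})

test_that("declining a mandatory module rejects the capture", {
  sys <- base_system(core_mandatory = TRUE)
  expect_error(record_consent(sys, "pseudonym:P1", "study/consent/1.0", "2020-01-01",
                              list(core = "DECLINED", bio = "ACCEPTED")),
               class = "MandatoryModuleNotAccepted")
  expect_length(sys$documents, 0L)
  # the archive switch stores it instead, but flagged invalid from the start
  sys2 <- base_system(core_mandatory = TRUE,
                      config = list(allow_incomplete_mandatory = TRUE))
  doc <- record_consent(sys2, "pseudonym:P1", "study/consent/1.0", "2020-01-01",
                        list(core = "DECLINED", bio = "ACCEPTED"))
  expect_false(is.null(doc$invalidation))
  res <- resolve_policy_status(sys2, "pseudonym:P1", "study/dna/1.0",
                               query_config(at_date = "2020-06-01"))
  expect_identical(res$raw_state, "INVALIDATED")
})

test_that("free-text fields validate typed values", {
  sys <- consent_system()
  create_domain(sys, "study", "S")
  define_policy(sys, "study/p/1.0", "p")
  define_module(sys, "study/m/1.0", "m", "", list("study/p/1.0"))
  define_template(sys, "study/t/1.0", "", "", list("study/m/1.0"),
                  free_text_defs = list(
                    free_text_field("facility", "STRING", required = TRUE),
                    free_text_field("visits", "INTEGER"),
                    free_text_field("weight", "DOUBLE"),
                    free_text_field("newsletter", "BOOLEAN"),
                    free_text_field("enrolled", "DATE")))
  ok <- record_consent(sys, "pseudonym:P1", "study/t/1.0", "2020-01-01",
                       list(m = "ACCEPTED"),
                       free_text = list(facility = "University Medicine",
                                        visits = "3", weight = "72.5",
                                        newsletter = "true", enrolled = "2020-01-01"))
  expect_identical(ok$free_text_values$visits, 3L)
  expect_identical(ok$free_text_values$weight, 72.5)
  expect_true(ok$free_text_values$newsletter)
  expect_s3_class(ok$free_text_values$enrolled, "Date")
  bad <- list(
    list(facility = "x", visits = "abc"),            # INTEGER given text
    list(facility = "x", enrolled = "not-a-date"),   # DATE malformed
    list(facility = "x", newsletter = "maybe"),      # BOOLEAN malformed
    list(facility = "x", weight = "heavy"),          # DOUBLE malformed
    list(visits = "1"),                              # required STRING missing
    list(facility = "x", unknown_field = "y")        # undeclared field
  )
  for (ft in bad) {
    expect_error(record_consent(sys, "pseudonym:P2", "study/t/1.0", "2020-01-01",
                                list(m = "ACCEPTED"), free_text = ft),
                 class = "FreeTextValidation")
  }
})

test_that("withdrawal creates a new latest versioned document", {
  sys <- base_system()
  first <- accept_all(sys, "pseudonym:P1", date = "2020-01-01")
  wd <- record_withdrawal(sys, "pseudonym:P1", "study", "FULL", "2021-06-01")
  expect_length(sys$documents, 2L)                          # append-only: both kept
  expect_identical(wd$withdrawal_of, first$document_id)
  expect_true(all(unlist(wd$policy_states) == "WITHDRAWN"))
  # self-containment: the withdrawal re-states every previously answered policy
  expect_setequal(names(wd$policy_states), names(first$policy_states))
  # the original document is untouched
  expect_true(all(unlist(get_document(sys, first$document_id)$policy_states) == "ACCEPTED"))
  expect_error(record_withdrawal(sys, "pseudonym:P9", "study", "FULL", "2021-06-01"),
               class = "NoPriorConsent")
  expect_error(record_withdrawal(sys, "pseudonym:P1", "study",
                                 list("study/never_asked/1.0"), "2021-07-01"),
               class = "UnknownPolicyInScope")
})

test_that("partial withdrawal carries every other answer forward", {
  sys <- base_system()
  accept_all(sys, "pseudonym:P1", date = "2020-01-01")
  wd <- record_withdrawal(sys, "pseudonym:P1", "study", list("study/store/1.0"),
                          "2021-06-01")
  expect_identical(wd$policy_states[["study/store/1.0"]], "WITHDRAWN")
  expect_identical(wd$policy_states[["study/collect/1.0"]], "ACCEPTED")
  expect_identical(wd$policy_states[["study/dna/1.0"]], "ACCEPTED")
  # module-scoped withdrawal expands to the module's policies
  wd2 <- record_withdrawal(sys, "pseudonym:P1", "study", list("study/bio/1.0"),
                           "2021-07-01")
  expect_identical(wd2$policy_states[["study/dna/1.0"]], "WITHDRAWN")
  expect_identical(wd2$policy_states[["study/collect/1.0"]], "ACCEPTED")
  expect_identical(wd2$policy_states[["study/store/1.0"]], "WITHDRAWN")  # carried
})

test_that("permanent-withdrawal domains block re-consent of withdrawn policies", {
  sys <- base_system(domain_props = list(PERMANENT_WITHDRAWAL = "true"))
  accept_all(sys, "pseudonym:P1", date = "2020-01-01")
  record_withdrawal(sys, "pseudonym:P1", "study", list("study/dna/1.0"), "2020-06-01")
  expect_error(accept_all(sys, "pseudonym:P1", date = "2021-01-01"),
               class = "PermanentWithdrawalBlock")
  # without the property the same sequence is a legitimate re-consent
  sys2 <- base_system()
  accept_all(sys2, "pseudonym:P1", date = "2020-01-01")
  record_withdrawal(sys2, "pseudonym:P1", "study", list("study/dna/1.0"), "2020-06-01")
  expect_no_error(accept_all(sys2, "pseudonym:P1", date = "2021-01-01"))
})

test_that("invalidation is additive and newer valid consents keep governing", {
  sys <- base_system()
  d1 <- accept_all(sys, "pseudonym:P1", date = "2020-01-01")
  invalidate_document(sys, d1$document_id, "enrolment error", "2020-02-01")
  res <- resolve_policy_status(sys, "pseudonym:P1", "study/collect/1.0",
                               query_config(at_date = "2020-06-01"))
  expect_identical(res$raw_state, "INVALIDATED")
  expect_identical(res$quality, "DECLINED")
  expect_error(invalidate_document(sys, d1$document_id, "again", "2020-03-01"),
               class = "AlreadyInvalidated")
  expect_error(invalidate_document(sys, "doc-999999", "x", "2020-03-01"),
               class = "UnknownDocument")
  # replay check: a newer valid consent governs over the invalidated one
  accept_all(sys, "pseudonym:P1", date = "2020-05-01")
  res2 <- resolve_policy_status(sys, "pseudonym:P1", "study/collect/1.0",
                                query_config(at_date = "2020-06-01"))
  expect_identical(res2$raw_state, "ACCEPTED")
})

test_that("scan attachments support paper-based workflows", {
  sys <- base_system(domain_props = list(SCAN_SIZE_LIMIT = "256"))
  doc <- accept_all(sys, "pseudonym:P1")
  expect_length(documents_missing_scan(sys, "study"), 1L)
  attach_scan(sys, doc$document_id, tiny_pdf(), "application/pdf")
  expect_length(documents_missing_scan(sys, "study"), 0L)   # asynchronous upload done
  attach_scan(sys, doc$document_id, tiny_pdf(32L), "image/jpeg")
  scans <- list_scans(sys, doc$document_id)
  expect_identical(scans$content_type, c("application/pdf", "image/jpeg"))
  expect_error(attach_scan(sys, doc$document_id, tiny_pdf(), "image/png"),
               class = "UnsupportedContentType")
  expect_error(attach_scan(sys, doc$document_id, as.raw(seq_len(300) %% 256),
                           "application/pdf"),
               class = "ScanTooLarge")
})

test_that("raw EXPIRED is never stored and capture states are vetted", {
  sys <- base_system()
  expect_error(record_consent(sys, "pseudonym:P1", "study/consent/1.0", "2020-01-01",
                              list(core = "EXPIRED", bio = "ACCEPTED")),
               class = "UnknownState")
  expect_error(record_consent(sys, "pseudonym:P1", "study/consent/1.0", "2020-01-01",
                              list(core = "WITHDRAWN", bio = "ACCEPTED")),
               class = "UnknownState")
  expect_error(record_consent(sys, "pseudonym:P1", "study/consent/1.0", "2020-01-01",
                              list(core = "ACCEPTED")),
               class = "MissingModuleDecision")
})
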