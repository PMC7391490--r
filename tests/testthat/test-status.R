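# Status-engine resolution: precedence, version matching, expiration and
# the worked longitudinal scenarios.

test_that("query flags control version matching and unknown collapsing", {
  sys <- base_system()
  # consented under template v1, which never asked the follow-up policy
  accept_all(sys, "pseudonym:P1", template = "study/consent/1.0", date = "2020-01-01")
  res <- resolve_policy_status(sys, "pseudonym:P1", "study/followup/1.0",
                               query_config(ignore_version_number = TRUE,
                                            at_date = "2020-06-01"))
  expect_identical(res$raw_state, "UNKNOWN")       # never asked
  expect_null(res$source_document)                 # distinguishes from stored NOT_ASKED
  expect_identical(res$quality, "UNKNOWN")
  # unknown_as_decline collapses the unknown class for gate-keeping
  res2 <- resolve_policy_status(sys, "pseudonym:P1", "study/followup/1.0",
                                query_config(ignore_version_number = TRUE,
                                             unknown_as_decline = TRUE,
                                             at_date = "2020-06-01"))
  expect_identical(res2$quality, "DECLINED")
  expect_false(is_consented(sys, "pseudonym:P1", "study/followup/1.0",
                            query_config(unknown_as_decline = TRUE,
                                         at_date = "2020-06-01")))
  # a policy name foreign to the domain is an error, not UNKNOWN
  expect_error(resolve_policy_status(sys, "pseudonym:P1", "study/never_defined/1.0"),
               class = "UnknownPolicy")
})

test_that("the latest document governs under both weightings", {
  sys <- base_system()
  # same signer, two documents: older date on newer template version
  accept_all(sys, "pseudonym:P1", template = "study/consent/2.0", date = "2020-01-01")
  record_consent(sys, "pseudonym:P1", "study/consent/1.0", "2021-06-01",
                 list(core = "ACCEPTED", bio = "DECLINED"))
  d_date <- latest_document(sys, "pseudonym:P1", "study", at_date = "2022-01-01",
                            weighting = "DATE_THEN_VERSION")
  expect_identical(key_string(d_date$template), "study/consent/1.0")   # later date wins
  d_ver <- latest_document(sys, "pseudonym:P1", "study", at_date = "2022-01-01",
                           weighting = "VERSION_THEN_DATE")
  expect_identical(key_string(d_ver$template), "study/consent/2.0")    # higher version wins
  # same date: version breaks the tie under either weighting
  sys2 <- base_system()
  a <- record_consent(sys2, "pseudonym:P1", "study/consent/2.0", "2021-01-01",
                      list(core = "ACCEPTED", bio = "ACCEPTED"))
  record_consent(sys2, "pseudonym:P1", "study/consent/1.0", "2021-01-01",
                 list(core = "ACCEPTED", bio = "ACCEPTED"))
  for (w in c("DATE_THEN_VERSION", "VERSION_THEN_DATE")) {
    expect_identical(latest_document(sys2, "pseudonym:P1", "study",
                                     at_date = "2022-01-01", weighting = w)$document_id,
                     a$document_id)
  }
  expect_null(latest_document(sys2, "pseudonym:P9", "study", at_date = "2022-01-01"))
  # documents dated after the evaluation date are invisible
  expect_null(latest_document(sys2, "pseudonym:P1", "study", at_date = "2020-01-01"))
})

test_that("partial withdrawal leaves other policies accepted", {
  sys <- base_system()
  accept_all(sys, "pseudonym:P1", date = "2020-01-01")
  record_withdrawal(sys, "pseudonym:P1", "study", list("study/store/1.0"), "2021-06-01")
  cfg <- query_config(at_date = "2022-01-01")
  expect_identical(resolve_policy_status(sys, "pseudonym:P1", "study/store/1.0", cfg)$raw_state,
                   "WITHDRAWN")
  expect_identical(resolve_policy_status(sys, "pseudonym:P1", "study/store/1.0", cfg)$quality,
                   "DECLINED")
  # analyses based on the other policies can still be conducted
  expect_true(is_consented(sys, "pseudonym:P1", "study/collect/1.0", cfg))
  expect_true(is_consented(sys, "pseudonym:P1", "study/dna/1.0", cfg))
  # before the withdrawal date the original consent still governs
  expect_true(is_consented(sys, "pseudonym:P1", "study/store/1.0",
                           query_config(at_date = "2021-05-31")))
})

test_that("withdrawal locality: out-of-scope policies keep their resolution", {
  set.seed(42)
  for (rep in 1:10) {
    sys <- base_system()
    states <- sample(c("ACCEPTED", "DECLINED", "NOT_CHOSEN"), 2, replace = TRUE)
    record_consent(sys, "pseudonym:P1", "study/consent/1.0", "2020-01-01",
                   list(core = states[1], bio = states[2]))
    cfg <- query_config(at_date = "2022-01-01")
    all_pols <- c("study/collect/1.0", "study/store/1.0", "study/dna/1.0")
    scope <- sample(all_pols, sample(1:2, 1))
    answered_states <- vapply(all_pols, function(p)
      resolve_policy_status(sys, "pseudonym:P1", p, cfg)$raw_state, "")
    record_withdrawal(sys, "pseudonym:P1", "study", as.list(scope), "2021-01-01")
    for (p in setdiff(all_pols, scope)) {
      expect_identical(resolve_policy_status(sys, "pseudonym:P1", p, cfg)$raw_state,
                       answered_states[[p]])
    }
    for (p in scope) {
      expect_identical(resolve_policy_status(sys, "pseudonym:P1", p, cfg)$raw_state,
                       "WITHDRAWN")
    }
  }
})

test_that("validity periods expire accepted consents", {
  # template-level p1y30d: consent 2020-01-01 is valid through 2021-01-31
  sys <- base_system(domain_props = list(VALIDITY_PERIOD = "p1y30d"))
  accept_all(sys, "pseudonym:P1", date = "2020-01-01")
  on_last_day <- resolve_policy_status(sys, "pseudonym:P1", "study/collect/1.0",
                                       query_config(at_date = "2021-01-31"))
  expect_identical(on_last_day$raw_state, "ACCEPTED")
  expect_identical(on_last_day$expiry_date, as.Date("2021-01-31"))
  day_after <- resolve_policy_status(sys, "pseudonym:P1", "study/collect/1.0",
                                     query_config(at_date = "2021-02-01"))
  expect_identical(day_after$raw_state, "EXPIRED")
  expect_true(day_after$expired)
  expect_identical(day_after$quality, "DECLINED")
  expect_false(is_consented(sys, "pseudonym:P1", "study/collect/1.0",
                            query_config(at_date = "2021-02-01")))
  # only an ACCEPTED raw state can turn EXPIRED: a declined consent stays DECLINED
  sys2 <- base_system(domain_props = list(VALIDITY_PERIOD = "p1y"))
  record_consent(sys2, "pseudonym:P2", "study/consent/1.0", "2020-01-01",
                 list(core = "DECLINED", bio = "DECLINED"))
  expect_identical(resolve_policy_status(sys2, "pseudonym:P2", "study/collect/1.0",
                                         query_config(at_date = "2025-01-01"))$raw_state,
                   "DECLINED")
})

test_that("the earliest expiry wins across specification levels", {
  sys <- base_system(domain_props = list(VALIDITY_PERIOD = "p5y"))
  # module-level period is shorter than the domain's
  update_module(sys, "study/bio/1.0", properties = list(VALIDITY_PERIOD = "p1y"))
  doc <- accept_all(sys, "pseudonym:P1", date = "2020-03-10")
  # min-rule oracle: candidates are 2025-03-10 (domain) and 2021-03-10 (module)
  expect_identical(effective_expiry(sys, doc, "study/dna/1.0"), as.Date("2021-03-10"))
  # the core policies see only the domain-level period
  expect_identical(effective_expiry(sys, doc, "study/collect/1.0"), as.Date("2025-03-10"))
  # no validity specification anywhere: indefinitely valid
  sys2 <- base_system()
  doc2 <- accept_all(sys2, "pseudonym:P1", date = "2020-03-10")
  expect_null(effective_expiry(sys2, doc2, "study/collect/1.0"))
  # fixed-date specs cap dynamic ones when earlier
  sys3 <- base_system(domain_props = list(VALIDITY_PERIOD = "p5y",
                                          VALIDITY_FIXED_DATE = "2022-12-31"))
  doc3 <- accept_all(sys3, "pseudonym:P1", date = "2020-03-10")
  expect_identical(effective_expiry(sys3, doc3, "study/collect/1.0"),
                   as.Date("2022-12-31"))
})

test_that("birthdate-anchored validity expires on the day after the 18th birthday", {
  sys <- base_system(domain_props = list(VALIDITY_PERIOD_FROM_BIRTHDATE = "p18y"))
  set_signer_birthdate(sys, "pseudonym:CHILD", "2004-07-15")
  accept_all(sys, "pseudonym:CHILD", date = "2012-01-01")   # parental consent
  on_birthday <- resolve_policy_status(sys, "pseudonym:CHILD", "study/collect/1.0",
                                       query_config(at_date = "2022-07-15"))
  expect_identical(on_birthday$raw_state, "ACCEPTED")
  adult <- resolve_policy_status(sys, "pseudonym:CHILD", "study/collect/1.0",
                                 query_config(at_date = "2022-07-16"))
  expect_identical(adult$raw_state, "EXPIRED")
  expect_false(is_consented(sys, "pseudonym:CHILD", "study/collect/1.0",
                            query_config(at_date = "2022-07-16")))
  # the spec applies but no birthdate is on record
  accept_all(sys, "pseudonym:NOBIRTH", date = "2012-01-01")
  expect_error(resolve_policy_status(sys, "pseudonym:NOBIRTH", "study/collect/1.0",
                                     query_config(at_date = "2022-07-16")),
               class = "MissingBirthdate")
})

test_that("expiration is monotone unless a new consent intervenes", {
  sys <- base_system(domain_props = list(VALIDITY_PERIOD = "p1y"))
  accept_all(sys, "pseudonym:P1", date = "2020-01-01")
  dates <- as.Date("2021-01-02") + c(0, 30, 200, 700)
  for (d in as.list(dates)) {
    expect_identical(resolve_policy_status(sys, "pseudonym:P1", "study/collect/1.0",
                                           query_config(at_date = d))$raw_state,
                     "EXPIRED")
  }
  # a renewed consent resets the clock
  accept_all(sys, "pseudonym:P1", date = "2022-06-01")
  expect_identical(resolve_policy_status(sys, "pseudonym:P1", "study/collect/1.0",
                                         query_config(at_date = "2022-12-01"))$raw_state,
                   "ACCEPTED")
})

test_that("resolution is deterministic for identical history and config", {
  h <- generate_history(history_spec(seed = 11, n_participants = 8, p_withdrawal = 0.5))
  sys1 <- apply_history(h)
  sys2 <- apply_history(h)
  cfg <- query_config(at_date = "2021-06-30")
  for (p in list_policies(sys1, "synth")) {
    for (s in sprintf("pseudonym:P%04d", 1:8)) {
      r1 <- resolve_policy_status(sys1, s, p$key, cfg)
      r2 <- resolve_policy_status(sys2, s, p$key, cfg)
      expect_identical(r1$raw_state, r2$raw_state)
      expect_identical(r1$source_document, r2$source_document)
    }
  }
})
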