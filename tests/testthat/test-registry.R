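# Domains, the versioned catalogue, lifecycle and the definition-file
# round trip.

test_that("domains partition the catalogue", {
  sys <- consent_system()
  create_domain(sys, "nako", "National Cohort", list(), "pseudonym")
  expect_length(list_templates(sys, "nako"), 0L)  # fresh domain, empty catalogue
  expect_error(create_domain(sys, "nako", "again"), class = "DuplicateDomain")
  create_domain(sys, "dzhk", "Cardio registry")
  define_policy(sys, "nako/collect/1.0", "Collect?")
  expect_length(list_policies(sys, "nako"), 1L)
  expect_length(list_policies(sys, "dzhk"), 0L)
  # modules may not reach across domains
  expect_error(define_module(sys, "dzhk/core/1.0", "Core", "", list("nako/collect/1.0")),
               class = "UnknownPolicy")
  expect_error(list_policies(sys, "gani_med"), class = "UnknownDomain")
})

test_that("domains and templates accept arbitrary external properties", {
  sys <- consent_system()
  d <- create_domain(sys, "study_a", "A",
                     properties = list(VALIDITY_PERIOD = "p1y30d", STUDY_ARM = "B"))
  expect_identical(get_domain_property(sys, "study_a", "VALIDITY_PERIOD"), "p1y30d")
  expect_identical(get_domain_property(sys, "study_a", "STUDY_ARM"), "B")
  # a known key with an unparseable value is rejected ...
  expect_error(create_domain(sys, "study_b", "B", properties = list(VALIDITY_PERIOD = "q9")),
               class = "InvalidProperty")
  # ... an unknown key is preserved but flagged in the validation report
  rep <- validate_properties(list(MY_CUSTOM_KEY = "anything", SCAN_SIZE_LIMIT = "1024"))
  expect_false(rep$known[rep$key == "MY_CUSTOM_KEY"])
  expect_true(all(rep$valid))
  expect_error(validate_properties(list(SCAN_SIZE_LIMIT = "-3")), class = "InvalidProperty")
})

test_that("modules aggregate ordered policies", {
  sys <- consent_system()
  create_domain(sys, "study", "S")
  define_policy(sys, "study/collect/1.0", "Collect?")
  define_policy(sys, "study/transfer/1.0", "Transfer?")
  define_policy(sys, "study/store/1.0", "Store?")
  m <- define_module(sys, "study/proc/1.0", "Processing research data", "",
                     list("study/collect/1.0", "study/transfer/1.0", "study/store/1.0"))
  expect_identical(vapply(get_module(sys, "study/proc/1.0")$policies, key_string, ""),
                   c("study/collect/1.0", "study/transfer/1.0", "study/store/1.0"))
  expect_error(define_module(sys, "study/empty/1.0", "E", "", list()),
               class = "EmptyModule")
  expect_error(define_module(sys, "study/dup/1.0", "D", "",
                             list("study/collect/1.0", "study/collect/1.0")),
               class = "DuplicatePolicyInModule")
  expect_error(define_policy(sys, "study/collect/1.0", "again"), class = "DuplicateKey")
})

test_that("templates define reusable consent forms with header, modules and footer", {
  sys <- base_system()
  tpl <- get_template(sys, "study/consent/1.0")
  expect_identical(tpl$header, "Welcome")
  expect_identical(tpl$footer, "Thanks")
  expect_length(tpl$module_assignments, 2L)
  expect_identical(tpl$free_text_defs[[1]]$name, "treatment_facility")
  expect_identical(tpl$free_text_defs[[1]]$value_type, "STRING")
  expect_error(define_template(sys, "study/bad/1.0", "", "", list()),
               class = "EmptyTemplate")
  # the no-contradiction rule: one policy name at most once per form,
  # even via a different module or policy version
  define_module(sys, "study/core_alt/1.0", "Alt", "", list("study/collect/1.0"))
  expect_error(define_template(sys, "study/contradictory/1.0", "", "",
                               list("study/core/1.0", "study/core_alt/1.0")),
               class = "PolicyAppearsTwice")
  expect_error(define_template(sys, "study/ghost/1.0", "", "",
                               list("study/nonexistent/1.0")),
               class = "UnknownModule")
})

test_that("finalized entities reject mutation", {
  sys <- base_system()
  update_template(sys, "study/consent/1.0", header = "Dear participant")  # DRAFT: fine
  finalize(sys, "study/consent/1.0", "template")
  expect_error(update_template(sys, "study/consent/1.0", header = "changed"),
               class = "ImmutableEntity")
  expect_error(update_module(sys, "study/core/1.0", title = "changed"),
               class = "ImmutableEntity")
  expect_error(update_policy(sys, "study/collect/1.0", label = "changed"),
               class = "ImmutableEntity")
  # idempotent
  expect_no_error(finalize(sys, "study/consent/1.0", "template"))
  # deletion: FINALIZED entities can only be deprecated, never removed
  expect_error(delete_draft(sys, "study/consent/1.0", "template"),
               class = "ImmutableEntity")
  deprecate_entity(sys, "study/consent/1.0", "template")
  expect_length(list_templates(sys, "study"), 1L)                       # v2 still listed
  expect_length(list_templates(sys, "study", include_deprecated = TRUE), 2L)
  # DRAFT entities can be deleted
  define_policy(sys, "study/tmp/1.0", "temp")
  delete_draft(sys, "study/tmp/1.0", "policy")
  expect_error(get_policy(sys, "study/tmp/1.0"), class = "UnknownPolicy")
})

test_that("finalizing a template transitively finalizes its modules and policies", {
  sys <- base_system()
  finalize(sys, "study/consent/1.0", "template")
  # graph-walk oracle: collect reachable entities and check each lifecycle
  tpl <- get_template(sys, "study/consent/1.0")
  for (a in tpl$module_assignments) {
    expect_true(is_finalized(sys, a$module, "module"))
    for (p in get_module(sys, a$module)$policies) {
      expect_true(is_finalized(sys, p, "policy"))
    }
  }
  # entities not reachable from the template stay DRAFT
  expect_false(is_finalized(sys, "study/core/2.0", "module"))
  expect_false(is_finalized(sys, "study/followup/1.0", "policy"))
})

test_that("template listings order versions numerically", {
  sys <- consent_system()
  create_domain(sys, "study", "S")
  define_policy(sys, "study/p/1.0", "p")
  define_module(sys, "study/m/1.0", "m", "", list("study/p/1.0"))
  for (v in c("2.9.1", "1.0", "2.10.0", "2.2")) {
    define_template(sys, paste0("study/consent/", v), "", "", list("study/m/1.0"))
  }
  versions <- vapply(list_templates(sys, "study"), function(t) t$key$version, "")
  expect_identical(versions, c("1.0", "2.2", "2.9.1", "2.10.0"))
  # sort-oracle property: every adjacent pair honours compare_versions
  for (i in seq_len(length(versions) - 1L)) {
    expect_identical(compare_versions(versions[i], versions[i + 1L]), "LT")
  }
})

test_that("definition export/import round-trips the catalogue", {
  sys <- base_system(domain_props = list(VALIDITY_PERIOD = "p5y", SITE = "greifswald"))
  finalize(sys, "study/consent/1.0", "template")
  deprecate_entity(sys, "study/dna/1.0", "policy")
  json1 <- export_definitions(sys, "study")
  sys2 <- consent_system()
  import_definitions(sys2, json1)
  json2 <- export_definitions(sys2, "study")
  expect_identical(json1, json2)                       # byte-identical re-export
  # deep equality of the catalogue itself (storage order is incidental)
  by_key <- function(x) x[sort(names(x))]
  expect_identical(sys2$domains, sys$domains)
  expect_identical(by_key(sys2$policies), by_key(sys$policies))
  expect_identical(by_key(sys2$modules), by_key(sys$modules))
  expect_identical(by_key(sys2$templates), by_key(sys$templates))
  # lifecycle survived the trip
  expect_true(is_finalized(sys2, "study/consent/1.0", "template"))
})

test_that("the shipped example definition file imports cleanly", {
  path <- system.file("extdata", "example-definitions.json", package = "consentry")
  sys <- consent_system()
  expect_identical(import_definitions(sys, path), "demo_study")
  expect_length(list_templates(sys, "demo_study"), 1L)
  expect_identical(get_domain_property(sys, "demo_study", "VALIDITY_PERIOD"), "p1y30d")
  expect_true(is.list(definitions_schema()))
})
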