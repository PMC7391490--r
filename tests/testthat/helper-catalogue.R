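# Shared fixture builders: a small two-version study catalogue built in code.
#
# Version 1.0 of the consent form asks four policies in two modules;
# version 2.0 adds a follow-up policy to the core module, so participants
# consented under 1.0 were never asked it.

base_system <- function(domain_props = list(), core_mandatory = FALSE,
                        config = list()) {
  sys <- consent_system(config = config)
  create_domain(sys, "study", "Example study", properties = domain_props)
  define_policy(sys, "study/collect/1.0", "Collect health information?")
  define_policy(sys, "study/store/1.0", "Store health information?")
  define_policy(sys, "study/dna/1.0", "Allow DNA-based analyses?")
  define_policy(sys, "study/followup/1.0", "Contact you for follow-up?")
  define_module(sys, "study/core/1.0", "Processing research data", "",
                list("study/collect/1.0", "study/store/1.0"))
  define_module(sys, "study/bio/1.0", "Biosamples", "",
                list("study/dna/1.0"))
  define_module(sys, "study/core/2.0", "Processing research data", "",
                list("study/collect/1.0", "study/store/1.0", "study/followup/1.0"))
  define_template(sys, "study/consent/1.0", "Welcome", "Thanks",
                  list(list(module = "study/core/1.0", mandatory = core_mandatory),
                       list(module = "study/bio/1.0")),
                  free_text_defs = list(free_text_field("treatment_facility", "STRING")))
  define_template(sys, "study/consent/2.0", "Welcome", "Thanks",
                  list(list(module = "study/core/2.0", mandatory = core_mandatory),
                       list(module = "study/bio/1.0")))
  sys
}

accept_all <- function(sys, signer, template = "study/consent/1.0",
                       date = "2020-01-01", ...) {
  record_consent(sys, signer, template, date,
                 list(core = "ACCEPTED", bio = "ACCEPTED"), ...)
}

tiny_pdf <- function(n = 64L) as.raw(c(0x25, 0x50, 0x44, 0x46, seq_len(n) %% 256))
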