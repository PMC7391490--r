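# consentry

Modular informed-consent management for longitudinal research studies, as an
R package: a versioned, immutable catalogue of consent policies, modules and
templates; an append-only store of captured consent documents, partial and
full withdrawals and invalidations; and a deterministic status engine that
answers, for any participant, policy and date, "may we use this?"

## Who this is for

Data trustees, study data-management units and research-infrastructure
developers who need reproducible, auditable answers to consent questions:
which participants currently consent to a policy, which policies one
participant consents to, which digitized paper consents still lack a scan,
and a byte-stable export of pseudonyms with valid consents.

## The model

Consent is **modular**: a *policy* is one atomic permit/deny decision
("collect health information", "allow DNA analyses"); a *module* groups
coherent policies answered together and may be mandatory; a versioned
*template* is the complete form (header, ordered modules, footer, typed
free-text fields); a *domain* owns the catalogue and its configuration.
Captured documents are never edited: withdrawals append a new document that
re-states the signer's complete current will (withdrawn policies →
`WITHDRAWN`, everything else carried forward), and invalidations are
additive annotations.

The status engine resolves each (signer, policy, date) to one of **nine raw
states** — `ACCEPTED`, `DECLINED`, `UNKNOWN`, `NOT_ASKED`, `NOT_CHOSEN`,
`WITHDRAWN`, `INVALIDATED`, `REFUSED`, `EXPIRED` — by latest-document
precedence (configurable date/version weighting), with expiry computed at
query time from validity specifications (fixed date, period from consent
such as `p1y30d`, period from birthdate such as `p18y`; earliest wins) and
aggregated into three quality classes (`ACCEPTED` / `DECLINED` / `UNKNOWN`)
for boolean queries. A policy added in template v2 resolves `UNKNOWN` for
participants consented under v1 — they were never asked.

## Worked example

```r
library(consentry)
sys <- consent_system()
create_domain(sys, "study", "Example study",
              properties = list(VALIDITY_PERIOD = "p1y30d"))
define_policy(sys, "study/collect/1.0", "Collect health information?")
define_policy(sys, "study/store/1.0",   "Store health information?")
define_module(sys, "study/core/1.0", "Processing research data", "",
              list("study/collect/1.0", "study/store/1.0"))
define_template(sys, "study/consent/1.0", "Welcome", "Thanks",
                list(list(module = "study/core/1.0", mandatory = FALSE)))

record_consent(sys, "pseudonym:P1", "study/consent/1.0", "2020-01-01",
               list(core = "ACCEPTED"))
resolve_policy_status(sys, "pseudonym:P1", "study/collect/1.0",
                      query_config(at_date = "2020-06-01"))
#> <resolution> study/collect/1.0 @ 2020-06-01
#>   raw: ACCEPTED     quality: ACCEPTED  source: doc-000001
#>   expiry: 2021-01-31

record_withdrawal(sys, "pseudonym:P1", "study",
                  list("study/store/1.0"), "2020-03-01")
resolve_policy_status(sys, "pseudonym:P1", "study/store/1.0",
                      query_config(at_date = "2020-06-01"))
#> <resolution> study/store/1.0 @ 2020-06-01
#>   raw: WITHDRAWN    quality: DECLINED  source: doc-000002
#>   expiry: 2021-03-31

cat(export_consented(sys, "study", config = query_config(at_date = "2020-06-01")))
#> "signer_id_type","signer_id","policy_domain","policy_name","policy_version","quality","consent_date","expiry_date"
#> "pseudonym","P1","study","collect","1.0","ACCEPTED","2020-03-01","2021-03-31"
```

The withdrawal produced a new governing document (`doc-000002`): `store` is
`WITHDRAWN` (quality `DECLINED`) while `collect` stays consented — a partial
withdrawal leaves analyses based on the remaining policies intact. The
domain's `p1y30d` validity runs from the governing document's date; after
2021-03-31 the `collect` resolution flips to `EXPIRED`.

The same operations are available through a JSON dispatcher
(`handle_request()`, with `operation_catalogue()` listing all 79 public
operations) and a CLI (`exec/consentry`; subcommands for
importing/exporting definition files, recording consents and withdrawals,
queries, exports, fixture generation and a JSON-lines serve mode).

## Package layout

- `R/` — registry, store, status engine, queries/exports, service
  dispatcher, CLI, audit log, synthetic-history generator and replay oracle
- `inst/extdata/` — requirements matrix, definition-file JSON schema,
  example definition document
- `vignettes/consent-engine.Rmd` — the model, its semantics and the design
  choices in detail
- `tests/testthat/` — unit, property and conformance suites
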