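---
title: "The consentry consent-status engine: model, semantics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The consentry consent-status engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consentry)
```

## The problem

Longitudinal health studies collect personal data and biosamples under
informed consent, and they must be able to answer — at any time, for any
participant and any single permission — "may we use this?" That question is
harder than it looks: consent forms evolve over template versions, new
questions are added that earlier participants were never asked, participants
withdraw fully or only partially, documents are invalidated retrospectively,
and some permissions expire by themselves (a study end date, or a parental
consent that lapses when the child comes of age). consentry models this life
cycle as an append-only event history plus a deterministic resolution
engine, so that every answer is reproducible from the stored documents
alone.

## The data model

The catalogue is organised in **domains** (a project, site or institution).
Within a domain:

* a **policy** is one atomic permit/deny decision ("collect health
  information", "allow DNA analyses") with the question text as its label;
* a **module** is an ordered group of coherent policies presented and
  answered together, e.g. "processing research data" = collect + transfer +
  store; a module can be flagged *mandatory* in a template, making its
  acceptance a necessary condition for participation;
* a **template** is one versioned consent form: header, ordered module
  assignments, footer, and typed free-text fields (`DATE`, `BOOLEAN`,
  `STRING`, `INTEGER`, `DOUBLE`).

Every catalogue entity is identified by `(domain, name, version)`. Versions
are dotted integers compared numerically (`2.10.0 > 2.9.1`). Two rules keep
recorded consent trustworthy:

1. **No contradiction**: across all modules of one template, each policy
   *name* may occur at most once — regardless of version, since two versions
   of the same question on one form could still be answered inconsistently.
2. **Immutability**: a FINALIZED entity never changes; edits require a new
   version. Finalizing a template transitively finalizes its modules and
   policies, and a template is finalized implicitly the first time a consent
   document references it, so immutability never depends on operator
   discipline. FINALIZED entities can be deprecated (hidden from listings)
   but never deleted.

## Captures, withdrawals, invalidations

A **consent document** records one capture event: signer (an identifier
type registered with the domain, typically a pseudonym issued by a trusted
third party, plus an opaque value), template version, the calendar date on
the form, and one raw state per policy. Decisions are given per module and
fanned out to the module's policies, with optional per-policy overrides; a
whole-document refusal fans `REFUSED` everywhere. Captures are either
`PAPER_DIGITIZED` (a signed paper form entered into the system, with PDF or
JPEG scans attachable asynchronously) or `ELECTRONIC`.

A **withdrawal** never edits history. It appends a new document in which the
withdrawn policies carry `WITHDRAWN` and every other policy the signer ever
answered in the domain carries its latest effective state forward. This
self-containment means the newest document alone suffices for resolution,
and it is what makes *partial* withdrawal safe: analyses based on the
remaining consented policies simply keep working. A consequence worth
stating explicitly: a withdrawal document may re-state policies from older
template versions than the one it references, so the rule "a document's
policies belong to its template" holds for consent captures but is relaxed
for withdrawal documents by design.

**Invalidation** (participant excluded retrospectively, or a formally
defective capture) is an additive annotation: the document stays on file,
but resolution treats its states as `INVALIDATED` and it never governs while
any valid document exists.

## The nine states and quality aggregation

Resolution depicts the participant's will in nine raw states: `ACCEPTED`,
`DECLINED`, `UNKNOWN` (the policy did not apply or could not be answered),
its two specialisations `NOT_ASKED` and `NOT_CHOSEN`, `WITHDRAWN`,
`INVALIDATED`, `REFUSED`, and `EXPIRED`. For boolean queries these aggregate
into three quality classes:

| quality    | raw states                                              |
|------------|---------------------------------------------------------|
| ACCEPTED   | ACCEPTED                                                |
| DECLINED   | DECLINED, WITHDRAWN, INVALIDATED, REFUSED, EXPIRED      |
| UNKNOWN    | UNKNOWN, NOT_ASKED, NOT_CHOSEN                          |

The `unknown_as_decline` flag collapses the unknown class to `DECLINED` —
the conservative gate-keeping reading, appropriate whenever an unanswered
policy must not grant access.

## Resolution semantics

`resolve_policy_status(sys, signer, policy, config)` proceeds as:

1. gather the signer's documents answering the policy — the exact versioned
   key, or any version of the name under `ignore_version_number`;
2. pick the governing document: by default order on (consent date, template
   version, capture timestamp) descending (`DATE_THEN_VERSION`; the
   alternative weighting `VERSION_THEN_DATE` puts template version first),
   with document id as the final deterministic tie-break;
3. report its stored raw state, replaced by `EXPIRED` when the state was
   `ACCEPTED` and the evaluation date lies after the effective expiry;
4. a signer never asked resolves `UNKNOWN` with no source document — this is
   exactly the longitudinal scenario where a policy was added in a later
   template version; stored `NOT_ASKED` is distinguishable by its source
   document;
5. when only invalidated documents answer, the resolution is `INVALIDATED`.

Resolution is a pure function of the history and the explicit `at_date`; no
hidden clock enters, so identical history and configuration always give
identical answers.

Three semantic choices here were genuinely open and are worth recording:

* **Only `ACCEPTED` can expire.** Expiry withdraws a permission; it cannot
  turn a refusal into anything else. A declined policy stays `DECLINED`
  forever regardless of validity periods.
* **Weighting default.** The precedence property names a version-and-date
  weighting without fixing its semantics; `DATE_THEN_VERSION` is the default
  because the participant's most recent expression of will should win, and
  the "every change results in a new latest consent" model is date-driven.
* **`EXPIRED` aggregates to `DECLINED`.** One could imagine a fourth class;
  keeping three classes with the raw state preserved in the resolution
  object lets callers that care distinguish expiry without complicating
  every boolean query.

## Validity and calendar arithmetic

Validity can be limited at domain, template, module and policy level through
three property keys: `VALIDITY_FIXED_DATE` (ISO date, e.g. the study end),
`VALIDITY_PERIOD` (a period anchored at the consent date) and
`VALIDITY_PERIOD_FROM_BIRTHDATE` (anchored at the signer's birthdate, e.g.
`p18y` for a parental consent lapsing at majority). Periods use the compact
grammar `p<N>y<N>m<N>d`. When several specifications apply, the **earliest
expiry wins** — the conservative combination that never extends a
permission beyond what any level allows. A consent is valid *on* its expiry
date and expired from the following day, so a `p18y` consent for a signer
born 2004-07-15 still answers `ACCEPTED` on the 18th birthday and `EXPIRED`
on 2022-07-16. A birthdate-anchored specification without a recorded
birthdate is an error (`MissingBirthdate`), never a silent pass.

Calendar arithmetic adds years, then months, then days; month-end overflow
clamps to the last day of the target month (Jan 31 + 1 month = Feb 28, or
Feb 29 in a leap year), then day addition is exact:

```{r}
add_period("2020-01-01", "p1y30d")
add_period("2020-01-31", "p1m")
```

Because a withdrawal document is a full re-statement of the signer's will,
a consent-date-anchored validity period on a carried-forward policy anchors
at the withdrawal document's date — the latest document *is* the current
consent, and its date restarts the validity window.

Domain properties form an open vocabulary: the keys the engine interprets
(`validate_properties()` lists them, including `PERMANENT_WITHDRAWAL`,
`SCAN_SIZE_LIMIT`, `MANDATORY_SCANS`) are validated strictly; unknown keys
are stored verbatim for application use and merely flagged in the
validation report.

## Capture-time guards

Two policy decisions are enforced at capture rather than query time. A
mandatory module whose decision is not `ACCEPTED` rejects the whole capture
(`MandatoryModuleNotAccepted`); the `allow_incomplete_mandatory` store
configuration instead archives such a document already invalidated, for
registries that must keep refusals on file without ever letting them govern.
And in a domain with `PERMANENT_WITHDRAWAL`, a new capture touching any
policy *name* the signer has withdrawn is rejected explicitly
(`PermanentWithdrawalBlock`) — an auditable failure rather than a silent
ignore, comparing by name because the withdrawal expressed the
participant's will about the question, not about a form version. The
property is applied at capture time; documents stored before the property
was set are untouched.

## The synthetic cohort generator and the replay oracle

`generate_history()` emulates the longitudinal usage pattern the engine is
built for: one domain whose consent template evolves over `k` versions, each
version adding a policy (so participants consented early are never asked the
additions — the canonical source of `UNKNOWN` resolutions); captures spread
over the first 60% of the study window with module-level decisions
(85% accepted) and occasional per-policy overrides (15% of policies); and
withdrawals at a configurable per-participant rate (default 0.1, half of
them partial), dated strictly after the capture. Everything is determined by
the seed; the same spec always yields the byte-identical event list.

What the generator deliberately does **not** emulate: multiple domains per
history, re-consent after withdrawal, invalidation events (the engine and
oracle support them; tests exercise them through fixed scenarios instead),
free-text payloads, scan uploads, and signers enrolling under more than one
identifier type. Passing the equivalence property therefore demonstrates the
precedence/expiry/aggregation semantics on realistic longitudinal shapes, not
robustness to operationally corrupt data.

`replay_oracle()` answers the same queries by a single linear scan over the
event list with no indexes and an independently written comparator,
fan-out, expiry and aggregation path; `oracle_agreement()` compares engine
and oracle over every (signer, policy) pair and every list query of a
history and reports the first divergence with the offending signer, policy
and both answers. The test suite runs this equivalence on 1000 seeded
histories of 4–12 participants each across both weightings, both unknown
modes, version-blind matching and a one-year expiring domain; the sizes keep
the whole check inside a few minutes while covering every semantic branch —
larger cohorts add documents, not new code paths.

## Service surface, audit and CLI

Every public operation is listed in a machine-readable catalogue
(`operation_catalogue()`, 79 operations) and reachable through the JSON
dispatcher `handle_request()`; `serve_requests()` binds the dispatcher to a
line-delimited JSON transport (the CLI's `serve` subcommand uses
stdin/stdout). The transport is deliberately plain: the testable contract is
the operation catalogue, not a wire dialect. There is no authentication —
actor identity is a caller-supplied string recorded in the audit log;
identity and authorisation belong to the surrounding infrastructure.

Every mutating operation appends exactly one audit record — for rejections
too, with the error name as outcome — so the log answers "who attempted
what, when, with which result" without ever being rewritten.

## Numerical and degenerate-input choices

* Ties in document precedence break on date, version, timestamp, then
  document id — total and deterministic.
* Capture timestamps default to the consent date plus a per-store sequence
  number; they matter only for same-day tie-breaking, since paper forms
  carry dates, not times. Callers may supply explicit timestamps.
* A withdrawal with no prior consent, a scope naming a never-asked policy,
  double invalidation, oversized or non-PDF/JPEG scans, malformed versions,
  periods, dates and property values are all rejected with named error
  conditions; nothing degrades silently.
* `p0y0m0d` is rejected: a zero validity period is almost certainly a
  configuration error, not "expires immediately".

## Known limitations

The store is in-memory with whole-file JSON persistence — right for a
library, a CLI and tests, not for concurrent multi-user service deployment.
Resolution scans a signer's documents linearly, which is exact but unindexed;
domains with millions of documents would want an indexed backend behind the
same semantics. Withdrawal scopes address policies and modules, not free-text
values; and the engine manages consent *documentation*, not legal
compliance — whether the consented wording covers an intended use remains a
question for researchers and ethics committees.
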