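Package: consentry
Title: Modular Informed-Consent Management Engine
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-sourced engine for managing modular informed consent in
    longitudinal research studies. Versioned, immutable catalogues of consent
    policies, modules and templates are organised in contextual domains;
    captured consent documents (digitized paper or fully electronic), partial
    and full withdrawals and invalidations form an append-only history; a
    status engine resolves the effective consent state of any participant and
    policy at any date under a nine-state vocabulary with configurable
    precedence, expiration (fixed dates and periods anchored at consent date
    or birthdate) and quality-class aggregation. Includes study-management
    queries, byte-stable consented-case exports, a JSON service dispatcher
    with operation introspection, a command-line interface, an append-only
    audit log, and a deterministic synthetic-history generator with an
    independent replay oracle for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
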