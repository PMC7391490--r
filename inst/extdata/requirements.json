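[
  {
    "id": 1,
    "requirement": "Support a general, study-wide consent form defined as a reusable digital template",
    "tests": ["templates define reusable consent forms with header, modules and footer"]
  },
  {
    "id": 2,
    "requirement": "Store individual filled-in participant consents digitally",
    "tests": ["record_consent stores an individual participant document"]
  },
  {
    "id": 3,
    "requirement": "Depict each consent status clearly for use-and-access decisions",
    "tests": [
      "the consent state vocabulary has exactly nine states",
      "quality aggregation maps each raw state to its class"
    ]
  },
  {
    "id": 4,
    "requirement": "Allow the participant to change their will at any time; every change yields a new latest, versioned consent",
    "tests": ["withdrawal creates a new latest versioned document"]
  },
  {
    "id": 5,
    "requirement": "Support consent exclusions: specific purposes can be declined under the opt-in model",
    "tests": ["a participant can decline an optional module"]
  },
  {
    "id": 6,
    "requirement": "Allow any number of engine-specific and external properties on catalogue entities",
    "tests": ["domains and templates accept arbitrary external properties"]
  },
  {
    "id": 7,
    "requirement": "Support typed free-text fields (DATE, BOOLEAN, STRING, INTEGER, DOUBLE) on templates",
    "tests": ["free-text fields validate typed values"]
  },
  {
    "id": 8,
    "requirement": "Support full and partial withdrawal in line with the right to withdraw",
    "tests": ["partial withdrawal leaves other policies accepted"]
  },
  {
    "id": 9,
    "requirement": "Version every policy, module and template; finalized versions are immutable",
    "tests": [
      "version comparison orders dotted versions numerically",
      "finalized entities reject mutation"
    ]
  },
  {
    "id": 10,
    "requirement": "Offer freely configurable automatable status queries (version matching, unknown-as-decline)",
    "tests": ["query flags control version matching and unknown collapsing"]
  },
  {
    "id": 11,
    "requirement": "Combine policies into modules for a fine-granular depiction of the expressed consent",
    "tests": ["modules aggregate ordered policies"]
  },
  {
    "id": 12,
    "requirement": "Support mandatory policies/modules as a necessary condition for participation",
    "tests": ["declining a mandatory module rejects the capture"]
  },
  {
    "id": 13,
    "requirement": "Automated search and query of consents, policies and identifiers for data trustees",
    "tests": [
      "study management queries answer the data-trustee catalogue",
      "participants consented to a policy excludes later withdrawals"
    ]
  },
  {
    "id": 14,
    "requirement": "Export consented cases, e.g. pseudonym lists with valid consents",
    "tests": ["consented-case export is byte-stable CSV"]
  },
  {
    "id": 15,
    "requirement": "Integrate paper-based workflows by attaching scans to digital consents",
    "tests": ["scan attachments support paper-based workflows"]
  },
  {
    "id": 16,
    "requirement": "Manage multiple domains (projects, sites, countries) with separate catalogues",
    "tests": ["domains partition the catalogue"]
  },
  {
    "id": 17,
    "requirement": "Support the common application scenarios through an intuitive operable interface",
    "tests": [
      "the operation catalogue exposes every public operation",
      "the CLI round-trips definitions and answers queries"
    ]
  },
  {
    "id": 18,
    "requirement": "Define the time of validity of a consent by fixed date or dynamic period at domain, template or module level",
    "tests": ["validity periods expire accepted consents"]
  }
]
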