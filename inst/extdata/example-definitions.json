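{
  "format": "consentry-definitions",
  "schema_version": "1.0",
  "domain": {
    "name": "demo_study",
    "label": "Demonstration cohort study",
    "properties": { "VALIDITY_PERIOD": "p1y30d" },
    "signer_id_types": ["pseudonym"],
    "logo": null,
    "deprecated": false
  },
  "policies": [
    {
      "key": { "domain": "demo_study", "name": "collect_data", "version": "1.0" },
      "label": "Do you consent to the collection of your health information?",
      "properties": {},
      "lifecycle": "DRAFT",
      "deprecated": false
    },
    {
      "key": { "domain": "demo_study", "name": "store_data", "version": "1.0" },
      "label": "Do you consent to long-term storage of your health information?",
      "properties": {},
      "lifecycle": "DRAFT",
      "deprecated": false
    },
    {
      "key": { "domain": "demo_study", "name": "contact_gp", "version": "1.0" },
      "label": "May we contact your general practitioner?",
      "properties": {},
      "lifecycle": "DRAFT",
      "deprecated": false
    }
  ],
  "modules": [
    {
      "key": { "domain": "demo_study", "name": "processing_research_data", "version": "1.0" },
      "title": "Processing research data",
      "text": "Collection and storage of health information for this study.",
      "policies": ["demo_study/collect_data/1.0", "demo_study/store_data/1.0"],
      "properties": {},
      "lifecycle": "DRAFT",
      "deprecated": false
    },
    {
      "key": { "domain": "demo_study", "name": "third_parties", "version": "1.0" },
      "title": "Contacting third parties",
      "text": "Authorisation to contact your general practitioner.",
      "policies": ["demo_study/contact_gp/1.0"],
      "properties": {},
      "lifecycle": "DRAFT",
      "deprecated": false
    }
  ],
  "templates": [
    {
      "key": { "domain": "demo_study", "name": "consent", "version": "1.0" },
      "header": "Informed consent for the demonstration cohort study.",
      "footer": "Thank you for supporting medical research.",
      "module_assignments": [
        { "module": "demo_study/processing_research_data/1.0", "mandatory": true, "display_order": 1 },
        { "module": "demo_study/third_parties/1.0", "mandatory": false, "display_order": 2 }
      ],
      "free_text_defs": [
        { "name": "treatment_facility", "value_type": "STRING", "required": false, "label": "Treatment facility" }
      ],
      "properties": {},
      "template_kind": "CONSENT",
      "lifecycle": "DRAFT",
      "deprecated": false
    }
  ]
}
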