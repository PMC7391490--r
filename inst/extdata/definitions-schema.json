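{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "consentry definition document",
  "description": "A domain's complete consent catalogue: the domain record plus its versioned policies, modules and templates. Exported by export_definitions(), accepted by import_definitions(); the round trip is lossless.",
  "type": "object",
  "required": ["format", "schema_version", "domain", "policies", "modules", "templates"],
  "properties": {
    "format": { "const": "consentry-definitions" },
    "schema_version": { "type": "string" },
    "domain": {
      "type": "object",
      "required": ["name"],
      "properties": {
        "name": { "type": "string", "minLength": 1 },
        "label": { "type": "string" },
        "properties": { "type": "object", "additionalProperties": { "type": "string" } },
        "signer_id_types": { "type": "array", "items": { "type": "string" } },
        "logo": { "type": ["string", "null"], "description": "base64-encoded PNG/JPEG blob" },
        "deprecated": { "type": "boolean" }
      }
    },
    "policies": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["key", "label"],
        "properties": {
          "key": { "$ref": "#/$defs/key" },
          "label": { "type": "string" },
          "properties": { "type": "object", "additionalProperties": { "type": "string" } },
          "lifecycle": { "enum": ["DRAFT", "FINALIZED"] },
          "deprecated": { "type": "boolean" }
        }
      }
    },
    "modules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["key", "title", "policies"],
        "properties": {
          "key": { "$ref": "#/$defs/key" },
          "title": { "type": "string" },
          "text": { "type": "string" },
          "policies": {
            "type": "array",
            "minItems": 1,
            "items": { "type": "string", "pattern": "^[^/]+/[^/]+/[^/]+$" }
          },
          "properties": { "type": "object", "additionalProperties": { "type": "string" } },
          "lifecycle": { "enum": ["DRAFT", "FINALIZED"] },
          "deprecated": { "type": "boolean" }
        }
      }
    },
    "templates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["key", "module_assignments"],
        "properties": {
          "key": { "$ref": "#/$defs/key" },
          "header": { "type": "string" },
          "footer": { "type": "string" },
          "module_assignments": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["module"],
              "properties": {
                "module": { "type": "string", "pattern": "^[^/]+/[^/]+/[^/]+$" },
                "mandatory": { "type": "boolean" },
                "display_order": { "type": "integer" }
              }
            }
          },
          "free_text_defs": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name", "value_type"],
              "properties": {
                "name": { "type": "string" },
                "value_type": { "enum": ["DATE", "BOOLEAN", "STRING", "INTEGER", "DOUBLE"] },
                "required": { "type": "boolean" },
                "label": { "type": "string" }
              }
            }
          },
          "properties": { "type": "object", "additionalProperties": { "type": "string" } },
          "template_kind": { "enum": ["CONSENT", "WITHDRAWAL"] },
          "lifecycle": { "enum": ["DRAFT", "FINALIZED"] },
          "deprecated": { "type": "boolean" }
        }
      }
    }
  },
  "$defs": {
    "key": {
      "type": "object",
      "required": ["domain", "name", "version"],
      "properties": {
        "domain": { "type": "string", "minLength": 1 },
        "name": { "type": "string", "minLength": 1 },
        "version": { "type": "string", "pattern": "^[0-9]+(\\.[0-9]+){0,3}$" }
      }
    }
  }
}
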