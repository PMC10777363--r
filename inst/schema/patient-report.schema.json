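{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://example.org/pgxvis/patient-report.schema.json",
  "title": "Patient PGx check report",
  "description": "Interchange document exported by a rule-based clinical decision support system after a pharmacogenomic plausibility check: patient demographics, prescriptions, gene-variant calls and per-drug guideline entries.",
  "type": "object",
  "required": ["patient"],
  "properties": {
    "patient": {
      "type": "object",
      "required": ["name"],
      "properties": {
        "name": { "type": "string" },
        "age": { "type": "number", "minimum": 0 },
        "sex": { "type": "string" },
        "bmi": { "type": "number", "exclusiveMinimum": 0 },
        "diagnoses": { "type": "array", "items": { "type": "string" } }
      }
    },
    "prescriptions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["drug_name"],
        "properties": {
          "drug_name": { "type": "string", "minLength": 1 },
          "drug_cas": { "type": "string", "pattern": "^[0-9]{2,7}-[0-9]{2}-[0-9]$" },
          "brand_name": { "type": "string" }
        }
      }
    },
    "gene_variants": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene", "diplotype"],
        "properties": {
          "gene": { "type": "string", "minLength": 1 },
          "diplotype": { "type": "string", "pattern": "^\\*[A-Za-z0-9]+/\\*[A-Za-z0-9]+$" },
          "activity_score": { "type": "number", "minimum": 0 }
        }
      }
    },
    "guidelines": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene", "severity"],
        "anyOf": [
          { "required": ["drug_name"] },
          { "required": ["drug_cas"] }
        ],
        "properties": {
          "gene": { "type": "string", "minLength": 1 },
          "diplotype": { "type": "string" },
          "activity_score": { "type": "number", "minimum": 0 },
          "metabolizer_status": {
            "type": "string",
            "description": "PM/IM/NM(EM)/UM abbreviation or spelled-out form; normalized on parse"
          },
          "drug_name": { "type": "string" },
          "drug_cas": { "type": "string" },
          "recommendation_text": { "type": "string" },
          "recommendation_category": {
            "type": "string",
            "description": "free text; normalized to increase_dose/decrease_dose/avoid/standard/other"
          },
          "severity": { "type": "integer", "minimum": 1, "maximum": 3 },
          "evidence_level": { "enum": ["1A", "1B", "2A", "2B", "3", "4", "NONE"] },
          "source_url": { "type": "string" },
          "effect_text": { "type": "string" },
          "source": { "type": "string" }
        }
      }
    }
  }
}
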