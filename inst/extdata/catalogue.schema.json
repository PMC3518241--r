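{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Drug-product catalogue",
  "description": "Schema for the JSON catalogue dialect. The equivalent delimited dialect is UTF-8, semicolon-separated, header row mandatory, decimal point; the 'ingredients' column holds parent:amount:unit[:salt] tokens joined by '+', and list-valued columns are comma-joined.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["product_id", "brand_name", "ingredients", "dosage_form",
                 "release", "route", "atc_codes", "indications", "on_hdf",
                 "divisibility"],
    "properties": {
      "product_id": {"type": "string", "minLength": 1},
      "brand_name": {"type": "string"},
      "ingredients": {
        "description": "parent:amount:unit[:salt] tokens, '+'-joined string or array",
        "oneOf": [
          {"type": "string", "pattern": "^[^:]+:[0-9.]+:(mg|microgram|IU)(:[^+]*)?([+][^:]+:[0-9.]+:(mg|microgram|IU)(:[^+]*)?)*$"},
          {"type": "array", "items": {"type": "string"}, "minItems": 1}
        ]
      },
      "dosage_form": {"type": "string"},
      "release": {"enum": ["immediate", "modified"]},
      "route": {"enum": ["oral", "parenteral", "inhaled", "topical", "other"]},
      "atc_codes": {
        "oneOf": [
          {"type": "string"},
          {"type": "array", "items": {"type": "string", "pattern": "^[A-Z][0-9]{2}[A-Z]{2}([0-9]{2})?$"}}
        ]
      },
      "indications": {
        "oneOf": [
          {"type": "string"},
          {"type": "array", "items": {"type": "string"}}
        ]
      },
      "on_hdf": {"oneOf": [{"type": "boolean"}, {"enum": ["0", "1"]}]},
      "divisibility": {"oneOf": [{"enum": [1, 2, 4]}, {"enum": ["1", "2", "4"]}]}
    }
  }
}
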