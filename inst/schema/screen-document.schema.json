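{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Cross-ome screen document",
  "description": "Export bundle of a pairwise microbe-immune interaction screen: run configuration, top table of surfaced relationships with per-cohort fitted-line geometry, and per-relationship sample-level arrays keyed by top-table row key.",
  "type": "object",
  "required": ["config", "topTable", "data"],
  "properties": {
    "config": {
      "type": "object",
      "required": ["referenceCohort", "thresholdType", "thresholdValue",
                   "minNonzero", "immuneTransform", "metricColumns", "seed",
                   "cohortColors"],
      "properties": {
        "referenceCohort": {"type": "string"},
        "thresholdType": {"enum": ["raw_p", "fdr_p"]},
        "thresholdValue": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "minNonzero": {"type": "integer", "minimum": 0},
        "immuneTransform": {"enum": ["none", "sqrt"]},
        "metricColumns": {
          "type": "array",
          "items": {"enum": ["F", "p", "pAdj", "interaction_p", "max_influence"]}
        },
        "seed": {"type": "integer"},
        "cohortColors": {
          "type": "object",
          "additionalProperties": {"type": "string", "pattern": "^#[0-9a-fA-F]{6}$"}
        }
      }
    },
    "topTable": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["key", "microbe", "immune"],
        "properties": {
          "key": {"type": "integer", "minimum": 1},
          "microbe": {"type": "string"},
          "immune": {"type": "string"},
          "F": {"type": ["number", "null"]},
          "p": {"type": ["number", "null"]},
          "pAdj": {"type": ["number", "null"]},
          "interaction_p": {
            "type": "object",
            "additionalProperties": {"type": ["number", "null"]}
          },
          "maxInfluence": {"type": ["number", "null"]},
          "n": {"type": "integer"},
          "cohortLines": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["cohort", "intercept", "slope", "xMin", "xMax"],
              "properties": {
                "cohort": {"type": "string"},
                "intercept": {"type": "number"},
                "slope": {"type": "number"},
                "xMin": {"type": "number"},
                "xMax": {"type": "number"},
                "gx0": {"type": "number"},
                "gy0": {"type": "number"},
                "gx1": {"type": "number"},
                "gy1": {"type": "number"}
              }
            }
          }
        }
      }
    },
    "data": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["x", "y", "cohort"],
        "properties": {
          "x": {"type": "array", "items": {"type": "number"}},
          "y": {"type": "array", "items": {"type": "number"}},
          "cohort": {"type": "array", "items": {"type": "string"}},
          "influence": {"type": "array", "items": {"type": "number"}},
          "xUnits": {"type": ["string", "null"]},
          "yUnits": {"type": ["string", "null"]}
        }
      }
    }
  }
}
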