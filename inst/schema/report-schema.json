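{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "alcsofa-report",
  "title": "alcsofa evaluation report",
  "version": "1.0",
  "type": "object",
  "required": ["schema_version", "config", "seed", "attrition",
               "n_analyzed", "alc_sofa_classes", "evaluation"],
  "properties": {
    "schema_version": {"type": "string", "const": "1.0"},
    "config": {"type": "object"},
    "seed": {"type": ["integer", "number"]},
    "attrition": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule", "n_excluded", "n_remaining"],
        "properties": {
          "rule": {"type": "string"},
          "n_excluded": {"type": "integer"},
          "n_remaining": {"type": "integer"}
        }
      }
    },
    "n_analyzed": {"type": "integer"},
    "alc_sofa_classes": {
      "type": "object",
      "properties": {
        "classes": {"type": "array"},
        "dropped": {"type": "array"},
        "logrank": {
          "type": ["object", "null"],
          "properties": {
            "chi2": {"type": "number"},
            "df": {"type": "integer"},
            "p": {"type": "number"}
          }
        }
      }
    },
    "evaluation": {
      "type": "object",
      "patternProperties": {
        "^h[0-9]+$": {
          "type": "object",
          "required": ["horizon_days", "status"],
          "properties": {
            "horizon_days": {"type": "number"},
            "status": {"type": "string"},
            "auc_new": {"type": "number"},
            "auc_old": {"type": "number"},
            "delong_z": {"type": "number"},
            "delong_p": {"type": "number"},
            "nri": {"type": "number"},
            "idi": {"type": "number"},
            "ci_nri": {"type": "array"},
            "ci_idi": {"type": "array"},
            "operating_point_new": {"type": "object"},
            "operating_point_old": {"type": "object"}
          }
        }
      }
    }
  }
}
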