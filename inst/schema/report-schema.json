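{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "halosucc analysis report",
  "type": "object",
  "required": ["flora_summary", "tdi", "family_loss", "family_gain",
               "bare_ground", "ec_screen", "traits", "nurse_plant",
               "lineage_ratio", "extinction_randomness", "prevalence",
               "provenance"],
  "properties": {
    "flora_summary": {
      "type": "object",
      "required": ["early", "late", "shared", "lost", "acquired"],
      "properties": {
        "early": {"type": "integer"},
        "late": {"type": "integer"},
        "shared": {"type": "integer"},
        "lost": {"type": "integer"},
        "acquired": {"type": "integer"}
      }
    },
    "tdi": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["group", "n_species", "tdi"],
        "properties": {
          "group": {"type": "string"},
          "n_species": {"type": "integer"},
          "tdi": {"type": ["number", "null"]}
        }
      }
    },
    "family_loss": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["family", "N", "K", "n", "k", "p_right", "p_left",
                     "p_bonferroni"]
      }
    },
    "family_gain": {"$ref": "#/$defs/test_result"},
    "bare_ground": {
      "type": "object",
      "additionalProperties": {"$ref": "#/$defs/test_result"}
    },
    "ec_screen": {
      "type": "object",
      "required": ["by_layer", "best"],
      "properties": {
        "by_layer": {"type": "array"},
        "best": {"$ref": "#/$defs/test_result"}
      }
    },
    "traits": {
      "type": "object",
      "additionalProperties": {"$ref": "#/$defs/test_result"}
    },
    "nurse_plant": {"$ref": "#/$defs/test_result"},
    "lineage_ratio": {"type": "object"},
    "extinction_randomness": {"$ref": "#/$defs/test_result"},
    "prevalence": {"type": "array"},
    "mpd_lost": {"$ref": "#/$defs/perm_summary"},
    "mpd_acquired": {"$ref": "#/$defs/perm_summary"},
    "mpd_families": {"$ref": "#/$defs/perm_summary"},
    "order_overrepresentation": {"$ref": "#/$defs/test_result"},
    "provenance": {
      "type": "object",
      "required": ["package_version", "seed", "n_perm"]
    }
  },
  "$defs": {
    "test_result": {
      "type": "object",
      "required": ["test", "p_value", "tail"],
      "properties": {
        "test": {"type": "string"},
        "statistic": {"type": ["number", "null"]},
        "p_value": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "p_adjusted": {"type": ["number", "null"]},
        "tail": {"enum": ["left", "right", "two-sided"]},
        "degenerate": {"type": "boolean"}
      }
    },
    "perm_summary": {
      "type": "object",
      "required": ["observed", "null_mean", "p_left", "p_right", "n_perm",
                   "seed", "pool_size"]
    }
  }
}
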