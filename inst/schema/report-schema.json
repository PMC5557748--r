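{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "symh2 study report",
  "type": "object",
  "required": ["h2_bayes", "provenance"],
  "properties": {
    "h2_bayes": {
      "type": "object",
      "required": ["mode", "mean", "sd", "ci95", "dic", "n_retained"],
      "properties": {
        "mode": {"type": "number", "minimum": 0, "maximum": 1},
        "mean": {"type": "number", "minimum": 0, "maximum": 1},
        "sd": {"type": "number", "minimum": 0},
        "ci95": {
          "type": "array", "minItems": 2, "maxItems": 2,
          "items": {"type": "number", "minimum": 0, "maximum": 1}
        },
        "dic": {"type": "number"},
        "n_retained": {"type": "integer", "minimum": 1},
        "dic_maternal": {"type": ["number", "null"]},
        "delta_dic": {"type": ["number", "null"]},
        "maternal_selected": {
          "type": ["string", "null"],
          "enum": ["maternal", "no_maternal", null]
        }
      }
    },
    "h2_regression": {
      "type": ["object", "null"],
      "required": ["mode", "slope", "se_slope", "intercept", "n", "h2"],
      "properties": {
        "mode": {"type": "string", "enum": ["midparent", "single_parent"]},
        "slope": {"type": "number"},
        "se_slope": {"type": "number", "minimum": 0},
        "intercept": {"type": "number"},
        "n": {"type": "integer", "minimum": 3},
        "h2": {"type": "number"},
        "warnings": {"type": ["array", "string", "null"]}
      }
    },
    "igv": {
      "type": ["object", "null"],
      "properties": {
        "n_otus_raw": {"type": "integer"},
        "n_otus_collapsed": {"type": "integer"},
        "h2_raw": {"type": "number"},
        "h2_collapsed": {"type": "number"},
        "h2_shift": {"type": "number"}
      }
    },
    "provenance": {
      "type": "object",
      "required": ["q", "seed", "abundance_threshold", "prior", "mcmc"],
      "properties": {
        "q": {"type": "number", "minimum": 0},
        "seed": {"type": "integer"},
        "abundance_threshold": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1},
        "prior": {"type": "object"},
        "mcmc": {"type": "object"}
      }
    }
  }
}
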