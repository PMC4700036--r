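{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tactostele analysis report",
  "type": "object",
  "required": ["provenance"],
  "properties": {
    "rindex": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["file", "r_value", "mean_nn", "density", "dims",
                     "n_points", "label"],
        "properties": {
          "file": {"type": "string"},
          "r_value": {"type": "number"},
          "mean_nn": {"type": "number"},
          "density": {"type": "number"},
          "dims": {"type": "integer", "enum": [1, 2]},
          "n_points": {"type": "integer"},
          "label": {"type": "string",
                    "enum": ["ordered", "random", "clustered"]}
        }
      }
    },
    "table1": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["n", "empirical", "theoretical", "fraction"],
        "properties": {
          "n": {"type": "integer"},
          "empirical": {"type": "number"},
          "theoretical": {"type": "number"},
          "fraction": {"type": "string"},
          "dynamics_exact": {"type": "number"}
        }
      }
    },
    "leafpdf": {
      "type": "object",
      "required": ["params", "support", "mass_simple", "mass_smoothed"]
    },
    "cellspace": {
      "type": "object",
      "required": ["n_free", "n_reps", "one_celled", "two_celled",
                   "frequency"]
    },
    "provenance": {
      "type": "object",
      "required": ["config", "config_md5", "seed", "package_version",
                   "timestamp"]
    }
  }
}
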