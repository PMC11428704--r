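{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "hemoflow run summary",
  "type": "object",
  "required": ["vessel_kind", "mode", "cells", "mass_balance", "indices",
               "wss_max"],
  "properties": {
    "vessel_kind": {"enum": ["straight", "arch", "dissected"]},
    "mode": {"enum": ["steady", "transient"]},
    "cells": {"type": "integer", "minimum": 1},
    "mass_balance": {
      "type": "object",
      "required": ["relative_imbalance"],
      "properties": {"relative_imbalance": {"type": "number", "minimum": 0}}
    },
    "indices": {
      "type": "object",
      "required": ["tawss_max", "osi_max", "rrt_max", "ecap_max"],
      "properties": {
        "tawss_max": {"type": "number", "minimum": 0},
        "tawss_mean": {"type": "number", "minimum": 0},
        "osi_max": {"type": "number", "minimum": 0, "maximum": 0.5},
        "rrt_max": {"type": "number", "minimum": 0},
        "ecap_max": {"type": "number", "minimum": 0}
      }
    },
    "wss_max": {"type": "number", "minimum": 0},
    "probes": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["min_mmHg", "mean_mmHg", "max_mmHg"]
      }
    }
  }
}
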