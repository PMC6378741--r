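{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "blisscreen heatmap payload",
  "type": "object",
  "required": ["drugs", "n_cell_lines", "matrix", "details"],
  "properties": {
    "drugs": {
      "type": "array",
      "items": { "type": "string" },
      "minItems": 3
    },
    "n_cell_lines": { "type": "integer", "minimum": 1 },
    "matrix": {
      "type": "array",
      "description": "one entry per unordered drug pair; absolute score drawn in the lower triangle, specificity score in the upper",
      "items": {
        "type": "object",
        "required": ["i", "j", "drug1", "drug2", "absolute_score", "specificity_score"],
        "properties": {
          "i": { "type": "integer", "minimum": 1 },
          "j": { "type": "integer", "minimum": 1 },
          "drug1": { "type": "string" },
          "drug2": { "type": "string" },
          "absolute_score": { "type": "integer", "minimum": 0 },
          "specificity_score": { "type": ["number", "null"] }
        }
      }
    },
    "details": {
      "type": "array",
      "description": "per-pair dot-plot payload: per cell line and dose, observed and Bliss-expected viabilities with delta-method error bars, singlet estimates, and call flags",
      "items": {
        "type": "object",
        "required": ["drug1", "drug2", "cells"],
        "properties": {
          "drug1": { "type": "string" },
          "drug2": { "type": "string" },
          "cells": {
            "type": "array",
            "items": {
              "type": "object",
              "required": [
                "cell_line", "dose_level", "viability", "observed_v_se",
                "expected_v", "expected_v_se", "v_hat_1", "singlet_1_se_v",
                "v_hat_2", "singlet_2_se_v", "z", "q_syn", "q_ant",
                "synergistic", "antagonistic"
              ]
            }
          }
        }
      }
    }
  }
}
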