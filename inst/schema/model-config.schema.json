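{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "bphcea model configuration",
  "description": "Overrides applied on top of the base-case parameterization. Omitted fields keep their defaults; unknown keys are rejected.",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "schema_version": { "const": 1 },
    "settings": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "cohort_size": { "type": "number", "exclusiveMinimum": 0, "default": 1000 },
        "horizon": { "type": "integer", "minimum": 1, "default": 10 },
        "cycle_length": { "const": 1 },
        "start_age": { "type": "number", "minimum": 40, "default": 70 },
        "discount_cost": { "type": "number", "minimum": 0, "exclusiveMaximum": 1, "default": 0.07 },
        "discount_utility": { "type": "number", "minimum": 0, "exclusiveMaximum": 1, "default": 0.03 },
        "wtp": { "type": "number", "minimum": 0, "default": 3701 },
        "discount_from": { "enum": ["year_0", "year_1"], "default": "year_1" },
        "half_cycle_correction": { "type": "boolean", "default": false },
        "crossover_timing": { "enum": ["end_of_cycle", "immediate"], "default": "end_of_cycle" },
        "freeze_age": { "type": "boolean", "default": false }
      }
    },
    "transitions": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "p_noncompliance_y1": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.3 },
        "p_drug_to_surgery_later": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.005 },
        "p_drug_to_pc": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.000836 },
        "p_surgery_to_pc": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.0011 },
        "pc_excess_death": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.18 },
        "surgery_death_addon_turp": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.001 },
        "surgery_death_addon_op": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.002 },
        "chemoprevention_rr": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.25 },
        "chemoprevention_cycles": { "type": "array", "items": { "type": "integer" }, "default": [1, 2] },
        "chemoprevention_enabled": { "type": "boolean", "default": true },
        "addon_first_year_only": { "type": "boolean", "default": true }
      }
    },
    "surgery_mix": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "share_turp": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.8 },
        "share_op": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.2 }
      }
    },
    "costs": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "drug_y1": { "type": "number", "minimum": 0, "default": 146.36 },
        "drug_later": { "type": "number", "minimum": 0, "default": 146.36 },
        "surg_y1": { "type": "number", "minimum": 0, "default": 840.96 },
        "surg_later": { "type": "number", "minimum": 0, "default": 9 },
        "pc_y1": { "type": "number", "minimum": 0, "default": 6141 },
        "pc_later": { "type": "number", "minimum": 0, "default": 2303 },
        "death": { "type": "number", "minimum": 0, "default": 0 },
        "infection_management": { "type": "number", "minimum": 0, "default": 0.71 },
        "tariff_sector": { "enum": ["blended", "public", "private"], "default": "blended" }
      }
    },
    "life_table": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "preset": { "enum": ["synthetic_default", "zero"] },
        "bands": {
          "type": "object",
          "properties": {
            "age_low": { "type": "array", "items": { "type": "number" } },
            "age_high": { "type": "array", "items": { "type": "number" } },
            "qx": { "type": "array", "items": { "type": "number", "minimum": 0, "exclusiveMaximum": 1 } }
          }
        }
      }
    },
    "utility": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "pc_utility": { "type": "number", "minimum": 0, "maximum": 1, "default": 0.62 },
        "baseline_ipss": { "type": "number", "minimum": 1, "maximum": 35, "default": 16.7 },
        "surgical_improvement": { "type": "number", "minimum": 0, "default": 8.5 },
        "complication_scale": { "type": "number", "minimum": 0, "default": 1 },
        "ipss_lookup": { "enum": ["interpolate", "round"], "default": "interpolate" },
        "use_observed_years": { "type": "boolean", "default": false }
      }
    }
  }
}
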