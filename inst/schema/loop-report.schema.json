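{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "venaloop validation report",
  "type": "object",
  "required": [
    "constant_flow", "pulsatile", "temperature", "heart_dimensions",
    "vessels", "path_lengths", "friction", "shear", "notes", "seed"
  ],
  "properties": {
    "constant_flow": {
      "type": "object",
      "required": ["trials", "slope", "intercept", "r_squared", "pass"],
      "properties": {
        "trials": {"type": "array"},
        "slope": {"type": "number"},
        "intercept": {"type": "number"},
        "r_squared": {"type": "number"},
        "pass": {"type": "boolean"}
      }
    },
    "pulsatile": {
      "type": "object",
      "required": [
        "theoretical_lpm", "measured_mean_lpm", "measured_sd_lpm",
        "n_trials", "n_cycles", "tolerance_lpm", "trials", "pass"
      ],
      "properties": {
        "theoretical_lpm": {"type": "number"},
        "measured_mean_lpm": {"type": "number"},
        "measured_sd_lpm": {"type": "number"},
        "n_trials": {"type": "integer"},
        "n_cycles": {"type": "integer"},
        "tolerance_lpm": {"type": "number"},
        "trials": {"type": "array"},
        "pass": {"type": "boolean"}
      }
    },
    "temperature": {
      "type": "object",
      "required": ["steady_c", "steady_rounded_c", "setpoint_c", "band_c", "pass"],
      "properties": {
        "steady_c": {"type": "number"},
        "steady_rounded_c": {"type": "number"},
        "setpoint_c": {"type": "number"},
        "band_c": {"type": "number"},
        "pass": {"type": "boolean"}
      }
    },
    "heart_dimensions": {
      "type": "object",
      "required": ["table", "all_pass"],
      "properties": {
        "table": {"type": "array"},
        "all_pass": {"type": "boolean"}
      }
    },
    "vessels": {
      "type": "object",
      "required": ["table", "all_pass"],
      "properties": {
        "table": {"type": "array"},
        "all_pass": {"type": "boolean"}
      }
    },
    "path_lengths": {
      "type": "object",
      "required": ["radial_cm", "femoral_cm", "target_cm", "pass"],
      "properties": {
        "radial_cm": {"type": "number"},
        "femoral_cm": {"type": "number"},
        "target_cm": {"type": "number"},
        "pass": {"type": "boolean"}
      }
    },
    "friction": {
      "type": "object",
      "required": ["mean_mu", "sd_mu", "n", "physiological_pass", "design_pass", "pass"],
      "properties": {
        "mean_mu": {"type": "number"},
        "sd_mu": {"type": "number"},
        "n": {"type": "integer"},
        "physiological_pass": {"type": "boolean"},
        "design_pass": {"type": "boolean"},
        "pass": {"type": "boolean"}
      }
    },
    "shear": {
      "type": "object",
      "required": ["flow_lpm", "table"],
      "properties": {
        "flow_lpm": {"type": "number"},
        "table": {"type": "array"}
      }
    },
    "notes": {"type": "array", "items": {"type": "string"}},
    "seed": {"type": "integer"}
  }
}
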