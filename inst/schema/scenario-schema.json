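{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "coilsteer scenario",
  "type": "object",
  "required": ["geometry", "coil", "drive"],
  "properties": {
    "geometry": {
      "type": "object",
      "required": ["domain_mm", "nerve_diameter_mm", "fascicles"],
      "properties": {
        "domain_mm": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}, "minItems": 3, "maxItems": 3},
        "nerve_diameter_mm": {"type": "number", "minimum": 0},
        "membrane_um": {"type": "number", "minimum": 0},
        "perineurium_um": {"type": "number", "minimum": 0},
        "fascicles": {
          "type": "object",
          "additionalProperties": {
            "type": "object",
            "required": ["center", "semi"],
            "properties": {
              "center": {"type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2},
              "semi": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}, "minItems": 2, "maxItems": 2},
              "rotation": {"type": "number"}
            }
          }
        },
        "regions": {
          "type": "object",
          "additionalProperties": {
            "type": "object",
            "required": ["fascicle", "poly"],
            "properties": {
              "fascicle": {"type": "string"},
              "poly": {"type": "array", "items": {"type": "array", "items": {"type": "number", "minimum": -1, "maximum": 1}}}
            }
          }
        }
      }
    },
    "conductivity": {
      "type": "object",
      "properties": {
        "sigma_x": {"type": "array", "items": {"type": "number", "minimum": 0}},
        "sigma_y": {"type": "array", "items": {"type": "number", "minimum": 0}},
        "sigma_z": {"type": "array", "items": {"type": "number", "minimum": 0}}
      },
      "description": "rows ordered: surrounding, membrane, epineurium, perineurium, fascicle; S/m"
    },
    "grid": {
      "type": "object",
      "properties": {
        "dx_mm": {"type": "number", "exclusiveMinimum": 0},
        "dyz_mm": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "coil": {
      "type": "object",
      "properties": {
        "inner_diameter_mm": {"type": "number", "exclusiveMinimum": 0},
        "outer_diameter_mm": {"type": "number", "exclusiveMinimum": 0},
        "length_mm": {"type": "number", "exclusiveMinimum": 0},
        "n_layers": {"type": "integer", "minimum": 1},
        "turns_per_layer": {"type": "integer", "minimum": 1},
        "wire_diameter_mm": {"type": "number", "exclusiveMinimum": 0},
        "segments_per_turn": {"type": "integer", "minimum": 8}
      }
    },
    "clearance_mm": {"type": "number", "minimum": 0},
    "drive": {
      "type": "object",
      "properties": {
        "I0_A": {"type": "number"},
        "f_Hz": {"type": "number", "exclusiveMinimum": 0},
        "slew_factor": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "tune": {
      "type": "object",
      "properties": {
        "w_max": {"type": "number", "exclusiveMinimum": 0},
        "w_step": {"type": "number", "exclusiveMinimum": 0},
        "refine_step": {"type": "number", "exclusiveMinimum": 0},
        "threshold": {"type": "number", "exclusiveMinimum": 0},
        "k": {"type": "number", "exclusiveMinimum": 0},
        "max_refine": {"type": "integer", "minimum": 1}
      }
    },
    "targets": {"type": "array", "items": {"type": "string"}},
    "tune_against": {"type": "array", "items": {"type": "string"}},
    "solver": {
      "type": "object",
      "properties": {
        "tol": {"type": "number", "exclusiveMinimum": 0},
        "maxit": {"type": "integer", "minimum": 1},
        "allow_unconverged": {"type": "boolean"}
      }
    },
    "seed": {"type": "integer"}
  }
}
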