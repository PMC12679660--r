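{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cortigen run configuration",
  "type": "object",
  "required": ["seed"],
  "additionalProperties": false,
  "properties": {
    "seed": {"type": "integer", "description": "mandatory master seed; expanded into per-stage child streams"},
    "steps": {"type": "integer", "minimum": 0},
    "out_dir": {"type": "string"},
    "log_level": {"enum": ["debug", "info", "warning", "error"]},
    "field": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "n": {"type": "integer", "minimum": 2},
        "layout": {"enum": ["grid", "random"]},
        "positions": {"type": ["array", "null"]},
        "spacing": {"type": "number", "exclusiveMinimum": 0},
        "frac_excitatory": {"type": "number", "minimum": 0, "maximum": 1},
        "v": {"type": "number", "exclusiveMinimum": 0,
              "description": "conduction speed, length units per step"},
        "dt": {"type": "number", "exclusiveMinimum": 0},
        "connection": {
          "type": "object",
          "additionalProperties": false,
          "properties": {
            "density": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
            "sigma": {"type": ["number", "string"],
                      "description": "distance decay of excitatory connection probability; \"Inf\" for none"},
            "density_i": {"type": "number", "minimum": 0, "maximum": 1},
            "sigma_i": {"type": ["number", "string"]}
          }
        },
        "gains": {
          "type": "object",
          "additionalProperties": false,
          "properties": {
            "eps0": {"type": "number", "minimum": 0},
            "g0": {"type": "number", "minimum": 0},
            "g_sd": {"type": "number", "minimum": 0},
            "rho0": {"type": "number", "minimum": 0},
            "headroom": {"type": "number", "exclusiveMinimum": 0,
                         "description": "competitive cap on each neuron's slow-gain row sum, times its initial value"}
          }
        },
        "single_population": {"type": "boolean"}
      }
    },
    "drive": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "amplitude": {"type": "number", "minimum": 0,
                      "description": "white-noise drive standard deviation, flux units"}
      }
    },
    "kernel": {
      "type": "object",
      "additionalProperties": false,
      "properties": {"tau": {"type": "number", "exclusiveMinimum": 0}}
    },
    "activation": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "theta": {"type": "number"},
        "slope": {"type": "number", "exclusiveMinimum": 0},
        "qmax": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "plasticity": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "enabled": {"type": "boolean"},
        "period": {"type": "integer", "minimum": 1},
        "T_eps": {"type": "number", "exclusiveMinimum": 0},
        "T_g": {"type": "number", "exclusiveMinimum": 0},
        "T_rho": {"type": "number", "exclusiveMinimum": 0},
        "T_theta": {"type": "number", "exclusiveMinimum": 0},
        "k_eps": {"type": "number", "minimum": 0},
        "eta_g": {"type": "number", "minimum": 0},
        "normalize": {"type": "boolean"},
        "anti_hebbian": {"type": "boolean"},
        "target": {"type": ["number", "string"],
                   "description": "\"adaptive\", \"auto\", or a flux constant"},
        "mode": {"enum": ["per_neuron", "population"]}
      }
    },
    "morph": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "n_patch": {"type": "integer", "minimum": 4},
        "n_local": {"type": "integer", "minimum": 4},
        "axon_scale_patch": {"type": "number", "exclusiveMinimum": 0},
        "axon_scale_local": {"type": "number", "exclusiveMinimum": 0},
        "w_synchrony": {"type": "number", "minimum": 0},
        "w_wiring": {"type": "number", "minimum": 0},
        "max_iter": {"type": "integer", "minimum": 1}
      }
    },
    "opmap": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "k": {"type": "number", "exclusiveMinimum": 0},
        "resolution": {"type": "number", "exclusiveMinimum": 0},
        "n_maps": {"type": "integer", "minimum": 1}
      }
    }
  }
}
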