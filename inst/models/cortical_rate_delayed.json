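{
  "name": "cortical_rate_delayed",
  "kind": "synapse",
  "params": {
    "w": {
      "default": 1,
      "unit": ""
    },
    "conduction_velocity": {
      "default": 500,
      "unit": "mm/s",
      "min": 1e-09
    }
  },
  "output_kind": "firing_rate",
  "rule": "w*w_edge*nu_pre",
  "protected": false
}
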