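{
  "name": "ampa",
  "kind": "synapse",
  "params": {
    "g": {
      "default": 1,
      "unit": "1/s",
      "min": 0
    },
    "E": {
      "default": 0,
      "unit": "mV"
    },
    "literal": {
      "default": 0,
      "unit": ""
    }
  },
  "output_kind": "voltage_rate",
  "rule": "-g*w_edge*n_pre*((1 - literal)*(V_post - E) + literal*(V_pre - E))",
  "protected": false
}
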