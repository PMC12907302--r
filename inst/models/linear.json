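{
  "name": "linear",
  "kind": "synapse",
  "params": {
    "w": {
      "default": 1,
      "unit": "1/s"
    }
  },
  "output_kind": "voltage_rate",
  "rule": "w*w_edge*V_pre",
  "protected": false
}
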