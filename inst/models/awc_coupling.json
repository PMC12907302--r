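{
  "name": "awc_coupling",
  "kind": "synapse",
  "params": {
    "w": {
      "default": 1,
      "unit": "mV/s"
    }
  },
  "output_kind": "voltage_rate",
  "rule": "w*w_edge*f_pre",
  "protected": false
}
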