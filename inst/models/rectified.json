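{
  "name": "rectified",
  "kind": "synapse",
  "params": {
    "w": {
      "default": 1,
      "unit": "1/s"
    },
    "theta_pre": {
      "default": -50,
      "unit": "mV"
    }
  },
  "output_kind": "voltage_rate",
  "rule": "w*w_edge*max(V_pre - theta_pre, 0)",
  "protected": false
}
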