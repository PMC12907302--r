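{
  "name": "gap_junction",
  "kind": "synapse",
  "params": {
    "w_gap": {
      "default": 10,
      "unit": "Hz",
      "min": 0
    }
  },
  "output_kind": "voltage_rate",
  "rule": "-w_gap*w_edge*(V_post - V_pre)",
  "protected": false
}
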