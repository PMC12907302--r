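{
  "name": "acetylcholine",
  "kind": "synapse",
  "params": {
    "g_A": {
      "default": 2,
      "unit": "nS",
      "min": 0
    },
    "gamma_A": {
      "default": 400,
      "unit": "nM^2",
      "min": 0
    },
    "V_A": {
      "default": 0,
      "unit": "mV"
    }
  },
  "output_kind": "current",
  "rule": "-g_A*(A_pre^2/(gamma_A + A_pre^2))*(V_post - V_A)*w_edge",
  "protected": false
}
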