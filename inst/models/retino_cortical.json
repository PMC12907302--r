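{
  "name": "retino_cortical",
  "kind": "synapse",
  "params": {
    "weight": {
      "default": 1,
      "unit": ""
    },
    "density_retina": {
      "default": 400,
      "unit": "1/mm^2",
      "min": 0
    },
    "density_cortex": {
      "default": 4000,
      "unit": "1/mm^2",
      "min": 1e-09
    }
  },
  "output_kind": "firing_rate",
  "rule": "weight*(density_retina/density_cortex)*firingRate_pre*w_edge",
  "protected": false
}
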