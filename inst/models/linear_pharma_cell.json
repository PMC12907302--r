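{
  "name": "linear_pharma_cell",
  "kind": "cell",
  "state_vars": [
    {
      "name": "V",
      "unit": "mV"
    }
  ],
  "params": {
    "C": {
      "default": 0.1,
      "unit": "nF",
      "min": 1e-09
    },
    "g_L": {
      "default": 1,
      "unit": "nS",
      "min": 0
    },
    "g_P": {
      "default": 0,
      "unit": "nS",
      "min": 0
    },
    "E_L": {
      "default": -60,
      "unit": "mV"
    },
    "E_P": {
      "default": 0,
      "unit": "mV"
    }
  },
  "input_slots": [
    "synaptic_current"
  ],
  "aux_functions": {},
  "rhs": {
    "V": "-(g_L + g_P)*V/C + I_syn/C + (g_L*E_L + g_P*E_P)/C"
  },
  "outputs": {
    "V": "V"
  },
  "protected": false
}
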