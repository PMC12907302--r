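{
  "name": "cortical_excitatory",
  "kind": "cell",
  "state_vars": [
    {
      "name": "V_pop",
      "unit": "mV"
    }
  ],
  "params": {
    "tau": {
      "default": 0.01,
      "unit": "s",
      "min": 1e-06
    },
    "baseline": {
      "default": 0,
      "unit": "mV"
    },
    "k_in": {
      "default": 0.5,
      "unit": "mV/Hz"
    },
    "nu_max": {
      "default": 100,
      "unit": "Hz",
      "min": 0
    },
    "g_t": {
      "default": 0.3,
      "unit": "1/mV",
      "min": 0
    },
    "theta": {
      "default": 10,
      "unit": "mV"
    }
  },
  "input_slots": [
    "synaptic_firing_rate"
  ],
  "aux_functions": {},
  "rhs": {
    "V_pop": "(-V_pop + baseline + k_in*FR_syn)/tau"
  },
  "outputs": {
    "V_pop": "V_pop",
    "nu": "nu_max*0.5*(1 + erf(g_t*(V_pop - theta)/sqrt(2)))"
  },
  "protected": true
}
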