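{
  "name": "bipolar_gain_control",
  "kind": "cell",
  "state_vars": [
    {
      "name": "A_B",
      "unit": "mV s"
    },
    {
      "name": "V",
      "unit": "mV"
    }
  ],
  "params": {
    "tau_AB": {
      "default": 0.2,
      "unit": "s",
      "min": 1e-06
    },
    "h_B": {
      "default": 1,
      "unit": "1/s",
      "min": 0
    },
    "theta_B": {
      "default": -50,
      "unit": "mV"
    },
    "tau_B": {
      "default": 0.05,
      "unit": "s",
      "min": 1e-06
    },
    "tau_ext": {
      "default": 0.02,
      "unit": "s",
      "min": 1e-06
    },
    "E_L": {
      "default": -60,
      "unit": "mV"
    }
  },
  "input_slots": [
    "external",
    "synaptic_voltage_rate"
  ],
  "aux_functions": {},
  "rhs": {
    "A_B": "-A_B/tau_AB + h_B*max(V - theta_B, 0)",
    "V": "-(V - E_L)/tau_B + ext/tau_ext + V_syn"
  },
  "outputs": {
    "V": "V",
    "A_B": "A_B",
    "bipolarResponse": "max(V - theta_B, 0)/(1 + A_B)"
  },
  "protected": false
}
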