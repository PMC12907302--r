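{
  "name": "ganglion_gain_control",
  "kind": "cell",
  "state_vars": [
    {
      "name": "V",
      "unit": "mV"
    },
    {
      "name": "A_G",
      "unit": "mV s"
    }
  ],
  "params": {
    "tau_L": {
      "default": 0.03,
      "unit": "s",
      "min": 1e-06
    },
    "V_L": {
      "default": -60,
      "unit": "mV"
    },
    "g_T": {
      "default": 0,
      "unit": "nS",
      "min": 0
    },
    "V_T": {
      "default": -40,
      "unit": "mV"
    },
    "C": {
      "default": 0.1,
      "unit": "nF",
      "min": 1e-09
    },
    "tau_G": {
      "default": 0.2,
      "unit": "s",
      "min": 1e-06
    },
    "H_G": {
      "default": 1,
      "unit": "1/s",
      "min": 0
    },
    "theta_G": {
      "default": -58,
      "unit": "mV"
    },
    "rate_gain": {
      "default": 1,
      "unit": "Hz/mV",
      "min": 0
    }
  },
  "input_slots": [
    "synaptic_voltage_rate"
  ],
  "aux_functions": {},
  "rhs": {
    "V": "-(V - V_L)/tau_L + V_syn - (g_T/C)*max(V - V_T, 0)",
    "A_G": "-A_G/tau_G + H_G*max(V - theta_G, 0)"
  },
  "outputs": {
    "V": "V",
    "A_G": "A_G",
    "firingRate": "rate_gain*max(V - theta_G, 0)/(1 + A_G)"
  },
  "protected": false
}
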