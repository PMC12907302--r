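{
  "name": "hodgkin_huxley",
  "kind": "cell",
  "state_vars": [
    {
      "name": "V",
      "unit": "mV"
    },
    {
      "name": "m",
      "unit": ""
    },
    {
      "name": "h",
      "unit": ""
    },
    {
      "name": "n",
      "unit": ""
    }
  ],
  "params": {
    "C": {
      "default": 1,
      "unit": "nF",
      "min": 1e-09
    },
    "g_Na": {
      "default": 120,
      "unit": "nS",
      "min": 0
    },
    "g_K": {
      "default": 36,
      "unit": "nS",
      "min": 0
    },
    "g_L": {
      "default": 0.3,
      "unit": "nS",
      "min": 0
    },
    "E_Na": {
      "default": 50,
      "unit": "mV"
    },
    "E_K": {
      "default": -77,
      "unit": "mV"
    },
    "E_L": {
      "default": -54.387,
      "unit": "mV"
    }
  },
  "input_slots": [
    "external",
    "synaptic_current"
  ],
  "aux_functions": {
    "alpha_m": "1000*0.1*(V + 40)/(1 - exp(-(V + 40)/10))",
    "beta_m": "1000*4*exp(-(V + 65)/18)",
    "alpha_h": "1000*0.07*exp(-(V + 65)/20)",
    "beta_h": "1000/(1 + exp(-(V + 35)/10))",
    "alpha_n": "1000*0.01*(V + 55)/(1 - exp(-(V + 55)/10))",
    "beta_n": "1000*0.125*exp(-(V + 65)/80)"
  },
  "rhs": {
    "V": "(-g_Na*m^3*h*(V - E_Na) - g_K*n^4*(V - E_K) - g_L*(V - E_L) + ext + I_syn)/C",
    "m": "alpha_m*(1 - m) - beta_m*m",
    "h": "alpha_h*(1 - h) - beta_h*h",
    "n": "alpha_n*(1 - n) - beta_n*n"
  },
  "outputs": {
    "V": "V",
    "m": "m",
    "h": "h",
    "n": "n"
  },
  "protected": false
}
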