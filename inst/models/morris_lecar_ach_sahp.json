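{
  "name": "morris_lecar_ach_sahp",
  "kind": "cell",
  "state_vars": [
    {
      "name": "V",
      "unit": "mV"
    },
    {
      "name": "N",
      "unit": ""
    },
    {
      "name": "A",
      "unit": "nM"
    },
    {
      "name": "R",
      "unit": ""
    },
    {
      "name": "S",
      "unit": ""
    }
  ],
  "params": {
    "C": {
      "default": 0.02,
      "unit": "nF",
      "min": 1e-09
    },
    "g_Ca": {
      "default": 4.4,
      "unit": "nS",
      "min": 0
    },
    "g_K": {
      "default": 8,
      "unit": "nS",
      "min": 0
    },
    "g_L": {
      "default": 2,
      "unit": "nS",
      "min": 0
    },
    "V_Ca": {
      "default": 120,
      "unit": "mV"
    },
    "V_K": {
      "default": -84,
      "unit": "mV"
    },
    "V_L": {
      "default": -60,
      "unit": "mV"
    },
    "V1": {
      "default": -1.2,
      "unit": "mV"
    },
    "V2": {
      "default": 18,
      "unit": "mV"
    },
    "V3": {
      "default": 2,
      "unit": "mV"
    },
    "V4": {
      "default": 30,
      "unit": "mV"
    },
    "phi": {
      "default": 40,
      "unit": "Hz",
      "min": 0
    },
    "I_bias": {
      "default": 95,
      "unit": "pA"
    },
    "mu_A": {
      "default": 10,
      "unit": "nM/s",
      "min": 0
    },
    "tau_Ach": {
      "default": 0.5,
      "unit": "s",
      "min": 1e-06
    },
    "theta_A": {
      "default": -20,
      "unit": "mV"
    },
    "k_A": {
      "default": 10,
      "unit": "mV"
    },
    "g_sAHP": {
      "default": 6,
      "unit": "nS",
      "min": 0
    },
    "E_K": {
      "default": -84,
      "unit": "mV"
    },
    "tau_R": {
      "default": 1.5,
      "unit": "s",
      "min": 1e-06
    },
    "tau_S": {
      "default": 1.5,
      "unit": "s",
      "min": 1e-06
    },
    "theta_R": {
      "default": -25,
      "unit": "mV"
    },
    "k_R": {
      "default": 10,
      "unit": "mV"
    }
  },
  "input_slots": [
    "external",
    "synaptic_current"
  ],
  "aux_functions": {
    "M_inf": "0.5*(1 + tanh((V - V1)/V2))",
    "N_inf": "0.5*(1 + tanh((V - V3)/V4))",
    "lam_N": "phi*cosh((V - V3)/(2*V4))",
    "T_A": "0.5*(1 + tanh((V - theta_A)/k_A))",
    "sig_R": "0.5*(1 + tanh((V - theta_R)/k_R))"
  },
  "rhs": {
    "V": "(-g_Ca*M_inf*(V - V_Ca) - g_K*N*(V - V_K) - g_L*(V - V_L) - g_sAHP*S^4*(V - E_K) + ext + I_syn + I_bias)/C",
    "N": "lam_N*(N_inf - N)",
    "A": "-A/tau_Ach + mu_A*T_A",
    "R": "(sig_R*(1 - R) - R)/tau_R",
    "S": "(R - S)/tau_S"
  },
  "outputs": {
    "V": "V",
    "N": "N",
    "A": "A",
    "R": "R",
    "S": "S"
  },
  "protected": false
}
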