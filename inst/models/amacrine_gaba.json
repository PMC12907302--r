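{
  "name": "amacrine_gaba",
  "kind": "cell",
  "state_vars": [
    {
      "name": "T",
      "unit": "nM"
    },
    {
      "name": "V",
      "unit": "mV"
    },
    {
      "name": "n",
      "unit": ""
    }
  ],
  "params": {
    "k_d": {
      "default": 10,
      "unit": "Hz",
      "min": 0
    },
    "k_p": {
      "default": 5,
      "unit": "nM/s",
      "min": 0
    },
    "E_N": {
      "default": -45,
      "unit": "mV"
    },
    "kappa_N": {
      "default": 5,
      "unit": "mV"
    },
    "tau_A": {
      "default": 0.05,
      "unit": "s",
      "min": 1e-06
    },
    "C_A": {
      "default": 0.05,
      "unit": "nF",
      "min": 1e-09
    },
    "beta_n": {
      "default": 5,
      "unit": "Hz",
      "min": 0
    },
    "alpha_n": {
      "default": 2,
      "unit": "1/(nM s)",
      "min": 0
    }
  },
  "input_slots": [
    "synaptic_current"
  ],
  "aux_functions": {},
  "rhs": {
    "T": "-k_d*T + k_p/(1 + exp(-(V - E_N)/kappa_N))",
    "V": "-V/tau_A + I_syn/C_A",
    "n": "-beta_n*n + alpha_n*T*(1 - n)"
  },
  "outputs": {
    "V": "V",
    "n": "n",
    "T": "T"
  },
  "protected": false
}
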