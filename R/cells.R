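# Hand-coded reference implementations of the pre-defined cell models.
# Each model also ships as a declarative JSON definition (inst/models/); the
# test suite checks the compiled definitions against these functions, so the
# two must agree to floating-point identity.
#
# All quantities are in the default unit system: time s, voltage mV,
# current pA, conductance nS, capacitance nF, frequency Hz, distance mm,
# molarity nM. Voltage-rate inputs (V_syn, V_ext) are mV/s.

#' Piecewise-linear rectifier
#'
#' \code{N(V) = V - theta} when \code{V > theta} (strictly), else 0. This is
#' the nonlinearity behind rectified conductances, rectified synapses and the
#' gain-control activity drives.
#'
#' @param V voltage, mV (vectorized).
#' @param theta threshold, mV.
#' @return rectified value, mV (non-negative).
#' @export
#' @examples
#' rectifier(-48, -50)  # 2
#' rectifier(-50, -50)  # 0
rectifier <- function(V, theta) {
  pmax(V - theta, 0)
}

#' Linear cell voltage derivative
#'
#' \code{dV/dt = -(V - E_L)/tau + V_syn}: a leaky integrator with
#' voltage-rate synaptic input. This is the plain bipolar/amacrine model.
#'
#' @param V membrane voltage, mV (vectorized).
#' @param params list with \code{tau} (s, > 0) and \code{E_L} (mV).
#' @param V_syn summed synaptic voltage-rate input, mV/s.
#' @return dV/dt in mV/s.
#' @export
linear_cell_rhs <- function(V, params, V_syn = 0) {
  -(V - params$E_L) / params$tau + V_syn
}

#' Linear cell with a tunable pharmacological conductance
#'
#' \code{dV/dt = -(g_L + g_P) V / C + I_syn / C + (g_L E_L + g_P E_P) / C}.
#' \code{g_P}/\code{E_P} model an ionic channel population sensitive to an
#' injected drug; \code{g_P = 0} recovers the leak-only cell.
#'
#' @param V membrane voltage, mV (vectorized).
#' @param params list with \code{C} (nF, > 0), \code{g_L}, \code{g_P} (nS),
#'   \code{E_L}, \code{E_P} (mV).
#' @param I_syn summed synaptic current, pA.
#' @return dV/dt in mV/s.
#' @export
pharma_cell_rhs <- function(V, params, I_syn = 0) {
  with(params, -(g_L + g_P) * V / C + I_syn / C + (g_L * E_L + g_P * E_P) / C)
}

#' Neurotransmitter-producing amacrine cell (GABA / AMPA)
#'
#' Linear amacrine with quasi-static transmitter production \code{T} and a
#' channel activation variable \code{n}:
#' \deqn{dT/dt = -k_d T + k_p / (1 + e^{-(V - E_N)/\kappa_N})}
#' \deqn{dV/dt = -V/\tau_A + I_{syn}/C_A}
#' \deqn{dn/dt = -\beta_n n + \alpha_n T (1 - n)}
#'
#' @param state list with vectors \code{T}, \code{V}, \code{n}.
#' @param params list with \code{k_d}, \code{k_p}, \code{E_N}, \code{kappa_N},
#'   \code{tau_A}, \code{C_A}, \code{beta_n}, \code{alpha_n}.
#' @param I_syn synaptic current, pA.
#' @return list of derivatives \code{T}, \code{V}, \code{n}.
#' @export
neurotransmitter_amacrine_rhs <- function(state, params, I_syn = 0) {
  with(params, list(
    T = -k_d * state$T + k_p / (1 + exp(-(state$V - E_N) / kappa_N)),
    V = -state$V / tau_A + I_syn / C_A,
    n = -beta_n * state$n + alpha_n * state$T * (1 - state$n)
  ))
}

#' Bipolar cell with gain control
#'
#' \deqn{dA_B/dt = -A_B/\tau_{AB} + h_B N_B(V)}
#' \deqn{dV/dt = -(V - E_L)/\tau_B + V_{ext}/\tau_{ext} + V_{syn}}
#' with \code{N_B} the rectifier at \code{theta_B}. The cell's pooled output
#' ("bipolarResponse", read by pooling synapses) is the rectified voltage
#' divided by the activity: \code{N_B(V) / (1 + A_B)}.
#'
#' @param state list with vectors \code{A_B}, \code{V}.
#' @param params list with \code{tau_AB}, \code{h_B}, \code{theta_B},
#'   \code{tau_B}, \code{tau_ext}, \code{E_L}.
#' @param V_ext OPL drive (mV; divided by \code{tau_ext} internally).
#' @param V_syn synaptic voltage-rate input, mV/s.
#' @return list of derivatives \code{A_B}, \code{V}.
#' @export
gain_control_bipolar_rhs <- function(state, params, V_ext = 0, V_syn = 0) {
  with(params, list(
    A_B = -state$A_B / tau_AB + h_B * rectifier(state$V, theta_B),
    V   = -(state$V - E_L) / tau_B + V_ext / tau_ext + V_syn
  ))
}

#' Ganglion cell with gain control
#'
#' \deqn{dV/dt = -(V - V_L)/\tau_L + V_{syn} - (g_T/C) G(V - V_T)}
#' \deqn{dA_G/dt = -A_G/\tau_G + H_G N_G(V)}
#' with \code{G} the rectifier at 0 and \code{N_G} the rectifier at
#' \code{theta_G}. The firing-rate output is divisive:
#' \code{rate_gain * N_G(V) / (1 + A_G)} (Hz, non-negative).
#'
#' @param state list with vectors \code{V}, \code{A_G}.
#' @param params list with \code{tau_L}, \code{V_L}, \code{g_T}, \code{V_T},
#'   \code{C}, \code{tau_G}, \code{H_G}, \code{theta_G}, \code{rate_gain}.
#' @param V_syn synaptic voltage-rate input, mV/s.
#' @return list of derivatives \code{V}, \code{A_G}.
#' @export
gain_control_ganglion_rhs <- function(state, params, V_syn = 0) {
  with(params, list(
    V   = -(state$V - V_L) / tau_L + V_syn -
      (g_T / C) * rectifier(state$V - V_T, 0),
    A_G = -state$A_G / tau_G + H_G * rectifier(state$V, theta_G)
  ))
}

#' Ganglion firing-rate output
#' @param state list with \code{V}, \code{A_G}.
#' @param params as in [gain_control_ganglion_rhs()].
#' @return firing rate, Hz.
#' @export
ganglion_firing_rate <- function(state, params) {
  params$rate_gain * rectifier(state$V, params$theta_G) / (1 + state$A_G)
}

#' Passive electrode (low-pass)
#'
#' \code{dV/dt = -V/tau + I_ext/C}; \code{I_ext} is the local pixel average
#' delivered by the prosthesis worker.
#'
#' @param V electrode potential, mV.
#' @param params list with \code{tau} (s) and \code{C} (nF).
#' @param I_ext input current, pA.
#' @return dV/dt in mV/s.
#' @export
electrode_rhs <- function(V, params, I_ext = 0) {
  -V / params$tau + I_ext / params$C
}

# Morris-Lecar steepness helpers
.ml_minf <- function(V, p) 0.5 * (1 + tanh((V - p$V1) / p$V2))
.ml_ninf <- function(V, p) 0.5 * (1 + tanh((V - p$V3) / p$V4))
.ml_lam  <- function(V, p) p$phi * cosh((V - p$V3) / (2 * p$V4))

#' Morris-Lecar neuron
#'
#' Standard two-variable Morris-Lecar form: calcium current with
#' instantaneous activation \code{M_inf(V)}, delayed-rectifier potassium
#' gated by \code{N}, and leak. Optional variants add acetylcholine
#' production (\code{ach = TRUE}: \code{dA/dt = -A/tau_Ach + mu_A T_A(V)}
#' with sigmoidal \code{T_A}) and a slow after-hyperpolarization potassium
#' current (\code{sahp = TRUE}: gating cascade \code{R -> S}, current
#' \code{-g_sAHP S^4 (V - E_K)}), the combination used to model starburst
#' amacrine cells during development.
#'
#' @param state list with vectors \code{V}, \code{N} (plus \code{A} when
#'   \code{ach}, \code{R}, \code{S} when \code{sahp}).
#' @param params list; core set \code{C, g_Ca, g_K, g_L, V_Ca, V_K, V_L,
#'   V1, V2, V3, V4, phi}, plus \code{I_bias} (pA), ACh set
#'   \code{mu_A, tau_Ach, theta_A, k_A}, sAHP set
#'   \code{g_sAHP, E_K, tau_R, tau_S, theta_R, k_R}.
#' @param I_ext external/synaptic current, pA.
#' @param ach,sahp logical variant flags.
#' @return list of derivatives matching the state.
#' @export
morris_lecar_rhs <- function(state, params, I_ext = 0, ach = FALSE,
                             sahp = FALSE) {
  p <- params
  V <- state$V
  I_ion <- -p$g_Ca * .ml_minf(V, p) * (V - p$V_Ca) -
    p$g_K * state$N * (V - p$V_K) -
    p$g_L * (V - p$V_L)
  if (sahp) I_ion <- I_ion - p$g_sAHP * state$S^4 * (V - p$E_K)
  d <- list(
    V = (I_ion + I_ext + p$I_bias) / p$C,
    N = .ml_lam(V, p) * (.ml_ninf(V, p) - state$N)
  )
  if (ach) {
    TA <- 0.5 * (1 + tanh((V - p$theta_A) / p$k_A))
    d$A <- -state$A / p$tau_Ach + p$mu_A * TA
  }
  if (sahp) {
    sigR <- 0.5 * (1 + tanh((V - p$theta_R) / p$k_R))
    d$R <- (sigR * (1 - state$R) - state$R) / p$tau_R
    d$S <- (state$R - state$S) / p$tau_S
  }
  d
}

# Hodgkin-Huxley rate functions, classical 1952 parameterization (6.3 C),
# rates converted from 1/ms to 1/s. The removable singularities of alpha_m
# and alpha_n (V = -40, -55 mV exactly) are left as written; the declarative
# twin uses the identical expressions.
.hh_alpha_m <- function(V) 1000 * 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10))
.hh_beta_m  <- function(V) 1000 * 4 * exp(-(V + 65) / 18)
.hh_alpha_h <- function(V) 1000 * 0.07 * exp(-(V + 65) / 20)
.hh_beta_h  <- function(V) 1000 / (1 + exp(-(V + 35) / 10))
.hh_alpha_n <- function(V) 1000 * 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10))
.hh_beta_n  <- function(V) 1000 * 0.125 * exp(-(V + 65) / 80)

#' Hodgkin-Huxley neuron (classical form)
#'
#' \deqn{C dV/dt = -g_{Na} m^3 h (V - E_{Na}) - g_K n^4 (V - E_K)
#'   - g_L (V - E_L) + I_{ext}}
#' with the classical squid-axon rate functions (no temperature scaling).
#'
#' @param state list with vectors \code{V}, \code{m}, \code{h}, \code{n}.
#' @param params list with \code{C} (nF), \code{g_Na}, \code{g_K}, \code{g_L}
#'   (nS), \code{E_Na}, \code{E_K}, \code{E_L} (mV).
#' @param I_ext external plus synaptic current, pA.
#' @return list of derivatives \code{V}, \code{m}, \code{h}, \code{n}.
#' @export
hodgkin_huxley_rhs <- function(state, params, I_ext = 0) {
  p <- params
  V <- state$V
  list(
    V = (-p$g_Na * state$m^3 * state$h * (V - p$E_Na) -
           p$g_K * state$n^4 * (V - p$E_K) -
           p$g_L * (V - p$E_L) + I_ext) / p$C,
    m = .hh_alpha_m(V) * (1 - state$m) - .hh_beta_m(V) * state$m,
    h = .hh_alpha_h(V) * (1 - state$h) - .hh_beta_h(V) * state$h,
    n = .hh_alpha_n(V) * (1 - state$n) - .hh_beta_n(V) * state$n
  )
}

#' Cortical column population (mean-rate)
#'
#' A documented rate model standing for an excitatory or inhibitory cortical
#' population: leaky integration of rate input,
#' \code{dV_pop/dt = (-V_pop + baseline + k_in * FR_syn) / tau}, with a
#' monotone non-negative sigmoidal rate transfer
#' \code{nu = nu_max * (1 + erf(g_t (V_pop - theta) / sqrt(2))) / 2}.
#' The full mean-field equations of the literature are not reproduced; all
#' parameters are exposed so users can refine the transfer.
#'
#' @param state list with vector \code{V_pop} (mV).
#' @param params list with \code{tau} (s), \code{baseline} (mV), \code{k_in}
#'   (mV per Hz), \code{nu_max} (Hz), \code{g_t} (1/mV), \code{theta} (mV).
#' @param FR_syn summed firing-rate input, Hz.
#' @return list with derivative \code{V_pop}.
#' @export
cortical_column_rhs <- function(state, params, FR_syn = 0) {
  with(params, list(
    V_pop = (-state$V_pop + baseline + k_in * FR_syn) / tau
  ))
}

#' Cortical column rate transfer
#' @param state list with \code{V_pop}.
#' @param params as in [cortical_column_rhs()].
#' @return firing rate nu, Hz (non-negative, monotone in V_pop).
#' @export
cortical_rate <- function(state, params) {
  with(params, nu_max * 0.5 * (1 + erf(g_t * (state$V_pop - theta) / sqrt(2))))
}

#' Amari-Wilson-Cowan unit
#'
#' \code{dV/dt = -V/tau + V_syn + H_ext}, where \code{H_ext} is the external
#' (OPL) drive plus the constant bias parameter \code{H_bias}; the sigmoidal
#' output read by the
#' coupling synapse is \code{f = (1 + erf(g V / sqrt(2))) / 2} with sigmoid
#' gain \code{g} (1/mV). \code{f(0) = 1/2}; \code{g = 0} freezes \code{f}
#' at 1/2.
#'
#' @param V voltage, mV (vectorized).
#' @param params list with \code{tau} (s), \code{g} (1/mV).
#' @param V_syn pooled coupling input, mV/s.
#' @param H_ext external (OPL) drive, mV/s.
#' @return dV/dt in mV/s.
#' @export
awc_cell_rhs <- function(V, params, V_syn = 0, H_ext = 0) {
  -V / params$tau + V_syn + H_ext
}

#' @rdname awc_cell_rhs
#' @export
awc_sigmoid <- function(V, params) {
  0.5 * (1 + erf(params$g * V / sqrt(2)))
}

# ---------------------------------------------------------------------------
# Dispatch tables used by the engine: every builtin cell type name maps to a
# vectorized rhs(state, params, inputs) and outputs(state, params) pair.
# `inputs` carries the canonical slots: ext, I_syn, V_syn, FR_syn.

.builtin_cell_rhs <- list(
  linear_cell = function(state, params, inputs)
    list(V = linear_cell_rhs(state$V, params, inputs$V_syn)),
  linear_pharma_cell = function(state, params, inputs)
    list(V = pharma_cell_rhs(state$V, params, inputs$I_syn)),
  amacrine_gaba = function(state, params, inputs)
    neurotransmitter_amacrine_rhs(state, params, inputs$I_syn),
  amacrine_ampa = function(state, params, inputs)
    neurotransmitter_amacrine_rhs(state, params, inputs$I_syn),
  bipolar_gain_control = function(state, params, inputs)
    gain_control_bipolar_rhs(state, params, inputs$ext, inputs$V_syn),
  ganglion_gain_control = function(state, params, inputs)
    gain_control_ganglion_rhs(state, params, inputs$V_syn),
  electrode = function(state, params, inputs)
    list(V = electrode_rhs(state$V, params, inputs$ext + inputs$I_syn)),
  morris_lecar = function(state, params, inputs)
    morris_lecar_rhs(state, params, inputs$ext + inputs$I_syn),
  morris_lecar_ach = function(state, params, inputs)
    morris_lecar_rhs(state, params, inputs$ext + inputs$I_syn, ach = TRUE),
  morris_lecar_ach_sahp = function(state, params, inputs)
    morris_lecar_rhs(state, params, inputs$ext + inputs$I_syn,
                     ach = TRUE, sahp = TRUE),
  hodgkin_huxley = function(state, params, inputs)
    hodgkin_huxley_rhs(state, params, inputs$ext + inputs$I_syn),
  cortical_excitatory = function(state, params, inputs)
    cortical_column_rhs(state, params, inputs$FR_syn),
  cortical_inhibitory = function(state, params, inputs)
    cortical_column_rhs(state, params, inputs$FR_syn),
  awc_cell = function(state, params, inputs)
    list(V = awc_cell_rhs(state$V, params, inputs$V_syn,
                          inputs$ext + params$H_bias))
)

.builtin_cell_outputs <- list(
  linear_cell = function(state, params) list(V = state$V),
  linear_pharma_cell = function(state, params) list(V = state$V),
  amacrine_gaba = function(state, params)
    list(V = state$V, n = state$n, T = state$T),
  amacrine_ampa = function(state, params)
    list(V = state$V, n = state$n, T = state$T),
  bipolar_gain_control = function(state, params)
    list(V = state$V, A_B = state$A_B,
         bipolarResponse = rectifier(state$V, params$theta_B) /
           (1 + state$A_B)),
  ganglion_gain_control = function(state, params)
    list(V = state$V, A_G = state$A_G,
         firingRate = ganglion_firing_rate(state, params)),
  electrode = function(state, params) list(V = state$V),
  morris_lecar = function(state, params) list(V = state$V, N = state$N),
  morris_lecar_ach = function(state, params)
    list(V = state$V, N = state$N, A = state$A),
  morris_lecar_ach_sahp = function(state, params)
    list(V = state$V, N = state$N, A = state$A, R = state$R, S = state$S),
  hodgkin_huxley = function(state, params)
    list(V = state$V, m = state$m, h = state$h, n = state$n),
  cortical_excitatory = function(state, params)
    list(V_pop = state$V_pop, nu = cortical_rate(state, params)),
  cortical_inhibitory = function(state, params)
    list(V_pop = state$V_pop, nu = cortical_rate(state, params)),
  awc_cell = function(state, params)
    list(V = state$V, f = awc_sigmoid(state$V, params))
)
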