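# Hand-coded reference implementations of the pre-defined synapse rules,
# input summation, and conduction-delay buffers. Like the cell models, each
# rule also ships as a declarative JSON twin checked against these.

#' Cholinergic (nicotinic) synaptic current
#'
#' \code{I = -g_A A_pre^2 / (gamma_A + A_pre^2) (V_post - V_A)}: sigmoidal
#' conductance in the pre-synaptic acetylcholine concentration, saturating
#' at \code{g_A}; \code{gamma_A} is the half-activation constant
#' (\code{A_pre^2 = gamma_A} gives half conductance).
#'
#' @param A_pre pre-synaptic ACh concentration, nM (>= 0, vectorized).
#' @param V_post post-synaptic voltage, mV.
#' @param p list with \code{g_A} (nS), \code{gamma_A} (nM^2), \code{V_A} (mV).
#' @return synaptic current, pA.
#' @export
ach_current <- function(A_pre, V_post, p) {
  -p$g_A * A_pre^2 / (p$gamma_A + A_pre^2) * (V_post - p$V_A)
}

#' Rectified synapse
#'
#' \code{w * max(V_pre - theta_pre, 0)} in mV/s: the pre-synaptic voltage is
#' thresholded once at \code{theta_pre} before scaling.
#'
#' @param V_pre pre-synaptic voltage, mV (vectorized).
#' @param p list with \code{w} (1/s) and \code{theta_pre} (mV).
#' @return voltage-rate contribution, mV/s.
#' @export
rectified_psp <- function(V_pre, p) {
  p$w * rectifier(V_pre, p$theta_pre)
}

#' Linear synapse
#'
#' \code{w * q_pre} in mV/s, where \code{q_pre} is the designated
#' pre-synaptic quantity: the voltage for plain cells, or the pooled
#' "bipolarResponse" output (\code{rectifier(V, theta_B)/(1 + A_B)}) when the
#' pooling variant reads a gain-control bipolar.
#'
#' @param V_pre pre-synaptic quantity (vectorized).
#' @param p list with \code{w}.
#' @return voltage-rate contribution, mV/s.
#' @export
linear_psp <- function(V_pre, p) {
  p$w * V_pre
}

#' Gap-junction coupling
#'
#' \code{-w_gap (V_post - V_pre)} in mV/s; \code{w_gap} in nS/nF = Hz.
#' Antisymmetric: a reciprocal pair with equal \code{w_gap} contributes a
#' zero instantaneous sum and diffusively pulls the two voltages together.
#'
#' @param V_pre,V_post voltages, mV (vectorized).
#' @param p list with \code{w_gap} (Hz, >= 0).
#' @return voltage-rate contribution, mV/s.
#' @export
gap_junction_psp <- function(V_pre, V_post, p) {
  -p$w_gap * (V_post - V_pre)
}

#' Cortical rate-to-rate coupling
#'
#' \code{w * nu_pre} (Hz); lateral cortical connectivity generated by the
#' graph module supplies the Gaussian geometric weight.
#'
#' @param nu_pre pre-synaptic population rate, Hz (vectorized).
#' @param p list with \code{w}.
#' @return firing-rate contribution, Hz.
#' @export
cortical_rate_coupling <- function(nu_pre, p) {
  p$w * nu_pre
}

#' Ligand-gated (GABA_A / AMPA) synapse
#'
#' \code{-g n_pre (V_drive - E)} in mV/s, with \code{n_pre} the pre-synaptic
#' channel activation. By default the driving voltage is the post-synaptic
#' one (the physiologically standard convention); \code{literal = 1} drives
#' with the pre-synaptic voltage instead.
#'
#' @param n_pre activation in [0, 1] (vectorized).
#' @param V driving voltage, mV (post-synaptic by default).
#' @param p list with \code{g} (1/s), \code{E} (mV).
#' @return voltage-rate contribution, mV/s.
#' @export
ligand_gated_psp <- function(n_pre, V, p) {
  -p$g * n_pre * (V - p$E)
}

#' Retino-cortical rate synapse
#'
#' \code{weight * (density_retina / density_cortex) * FR_pre}: ganglion-cell
#' firing rates scaled by the ratio of retinal to cortical cell densities
#' (defaults 400 and 4000 per mm^2).
#'
#' @param FR_pre pre-synaptic firing rate, Hz (>= 0, vectorized).
#' @param p list with \code{weight}, \code{density_retina},
#'   \code{density_cortex} (> 0).
#' @return firing-rate contribution, Hz.
#' @export
retino_cortical_rate <- function(FR_pre, p) {
  if (is.null(p$density_cortex) || p$density_cortex == 0) {
    stop(validation_error("retino-cortical synapse: density_cortex must be > 0"))
  }
  p$weight * (p$density_retina / p$density_cortex) * FR_pre
}

#' Discretized synaptic conduction delay
#'
#' The continuous delay is \code{d_syn / v_C} (distance over conduction
#' velocity); the engine is step-based, so it is discretized to the nearest
#' integer number of steps (minimum 0). A synapse type without a
#' \code{conduction_velocity} parameter is instantaneous: 0 steps.
#'
#' @param d_syn 2-D Euclidean pre-post distance, mm (>= 0, vectorized).
#' @param v_C conduction velocity, mm/s (> 0), or NULL/NA for an
#'   instantaneous synapse.
#' @param dt integration step, s.
#' @return integer number of delay steps.
#' @export
#' @examples
#' synaptic_delay(2, 1, 0.1)    # 2 s -> 20 steps
#' synaptic_delay(0.55, 1, 0.1) # 5.5 steps -> 6
#' synaptic_delay(1, NULL, 0.1) # instantaneous -> 0
synaptic_delay <- function(d_syn, v_C, dt) {
  if (is.null(v_C) || all(is.na(v_C))) return(rep(0L, length(d_syn)))
  if (any(v_C <= 0)) {
    stop(validation_error("conduction_velocity must be > 0"))
  }
  as.integer(round((d_syn / v_C) / dt))
}

# ---------------------------------------------------------------------------
# Delay buffers: per (layer, output) ring of past samples at step resolution.

#' Ring buffer of pre-synaptic output samples
#'
#' Holds the last \code{max_steps + 1} per-cell samples of one layer output.
#' Reading at delay 0 returns the current sample; buffers are pre-filled
#' with the output at t = 0 so early reads are well defined.
#'
#' @param init numeric vector, output values at t = 0 (one per cell).
#' @param max_steps largest delay (in steps) any edge reads.
#' @return object of class \code{"delay_buffer"}.
#' @export
delay_buffer <- function(init, max_steps) {
  n <- max_steps + 1L
  list(
    data = matrix(rep(init, n), nrow = length(init), ncol = n),
    head = 1L,   # column holding the current sample
    n_slots = n
  ) |> structure(class = "delay_buffer")
}

#' Push the current sample into a delay buffer
#' @param buf a [delay_buffer()].
#' @param values numeric vector, the layer output at the new current step.
#' @return the updated buffer.
#' @export
buffer_push <- function(buf, values) {
  buf$head <- if (buf$head == 1L) buf$n_slots else buf$head - 1L
  buf$data[, buf$head] <- values
  buf
}

#' Read delayed samples from a buffer
#' @param buf a [delay_buffer()].
#' @param cells integer cell indices (1-based).
#' @param delays integer delay in steps per requested cell (same length).
#' @return numeric vector of delayed samples.
#' @export
buffer_read <- function(buf, cells, delays) {
  cols <- ((buf$head - 1L + delays) %% buf$n_slots) + 1L
  buf$data[cbind(cells, cols)]
}

# ---------------------------------------------------------------------------
# Reference input summation (Eqs. 5-7 shape): a naive per-edge loop used as
# the oracle for the engine's vectorized path, and directly for tiny graphs.

#' Total synaptic input of one cell (brute-force reference)
#'
#' Sums every incoming edge's contribution into the three input slots
#' \code{I_syn} (pA), \code{V_syn} (mV/s) and \code{FR_syn} (Hz), evaluating
#' each edge's synapse rule on the pre-synaptic outputs (delayed samples must
#' already be resolved by the caller). This is the plain per-edge loop; the
#' engine's grouped/vectorized path is tested against it.
#'
#' @param edges data.frame with columns \code{synapse_type}, \code{weight}
#'   and \code{pre} (list-column of named lists of pre-synaptic output
#'   values), for the edges incoming to one cell.
#' @param post_out named list of the post-synaptic cell's output values.
#' @param registry a [model_registry()] resolving the synapse types.
#' @param params_override optional named list: synapse type -> parameter
#'   overrides.
#' @return list with scalars \code{I_syn}, \code{V_syn}, \code{FR_syn}.
#' @export
total_input <- function(edges, post_out, registry, params_override = list()) {
  acc <- list(I_syn = 0, V_syn = 0, FR_syn = 0)
  slot_of <- c(current = "I_syn", voltage_rate = "V_syn",
               firing_rate = "FR_syn")
  if (is.null(edges) || nrow(edges) == 0L) return(acc)
  for (k in seq_len(nrow(edges))) {
    def <- get_type(registry, edges$synapse_type[[k]])
    if (!identical(def$kind, "synapse")) {
      stop(validation_error(sprintf("'%s' is not a synapse type", def$name)))
    }
    p <- modifyList(as.list(def$params),
                    params_override[[def$name]] %||% list())
    pre_out <- edges$pre[[k]]
    missing_out <- setdiff(def$pre_refs, names(pre_out))
    if (length(missing_out)) {
      stop(validation_error(sprintf(
        "synapse '%s': pre-synaptic cell lacks output(s) %s",
        def$name, paste(missing_out, collapse = ","))))
    }
    val <- synapse_rule_fun(def)(pre_out, post_out, edges$weight[[k]], p)
    slot <- slot_of[[def$output_kind]]
    acc[[slot]] <- acc[[slot]] + val
  }
  acc
}
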