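# Scenario builders: ready-made graph + session pairs for the three shipped
# experiments (developmental retinal waves, a retino-cortical model, and an
# Amari-Wilson-Cowan field). Builders are deterministic given their
# arguments; initial-condition jitter is drawn under the explicit seed.

#' Retinal-waves scenario
#'
#' One layer of starburst amacrine cells (Morris-Lecar with acetylcholine
#' production and a slow after-hyperpolarization potassium current) coupled
#' intra-layer by cholinergic synapses on nearest-neighbor or Gaussian
#' connectivity, with no external input (worker "none"). Initial voltages
#' are jittered uniformly (seeded) to break the lattice symmetry, standing
#' in for the noise-driven wave nucleation of the biological system, since
#' the integration itself is deterministic.
#'
#' @param nx,ny lattice size (default 10 x 10).
#' @param connectivity \code{"nearest_neighbors"} or \code{"gaussian"}.
#' @param sigma_p Gaussian width (mm) when \code{connectivity = "gaussian"}.
#' @param spacing cell spacing, mm.
#' @param t_end,dt simulated duration and step, s.
#' @param seed seed for the initial-condition jitter.
#' @param params per-type parameter overrides merged into the session.
#' @return list with \code{graph} (a [sim_graph()]) and \code{session}
#'   (a [sim_session()]).
#' @export
build_retinal_waves <- function(nx = 10, ny = 10,
                                connectivity = c("nearest_neighbors",
                                                 "gaussian"),
                                sigma_p = 0.1, spacing = 0.05,
                                t_end = 5, dt = 5e-4, seed = 1,
                                params = list()) {
  connectivity <- match.arg(connectivity)
  stopifnot(nx >= 2, ny >= 2)
  sac <- layer_spec("sac", "morris_lecar_ach_sahp", nx, ny,
                    spacing = spacing, z = 0)
  edges <- if (connectivity == "nearest_neighbors") {
    connect(sac, sac, "nearest_neighbors", "acetylcholine", weight_const = 1)
  } else {
    connect(sac, sac, "gaussian", "acetylcholine", sigma_p = sigma_p)
  }
  set.seed(seed)
  n <- nx * ny
  graph <- sim_graph(
    layers = list(sac),
    edges = edges,
    initial_values = list(sac = list(
      V = stats::runif(n, -70, -40), N = 0, A = 0, R = 0, S = 0))
  )
  session <- sim_session(
    graph = graph, params = params, worker = "none", solver = "rk4",
    dt = dt, t_end = t_end, dt_record = max(dt, 5e-3),
    record = list(list(layer = "sac", var = "V", cells = "all"),
                  list(layer = "sac", var = "A", cells = "all")),
    seed = seed
  )
  list(graph = graph, session = session)
}

#' Retino-cortical scenario
#'
#' Five layers on matched grids: gain-control bipolar cells driven by the
#' OPL receptive-field response to a moving bar, amacrine cells providing
#' lateral inhibition (bipolars excite amacrines through rectified synapses,
#' amacrines inhibit bipolars and ganglion cells through linear synapses
#' with negative geometric weight), gain-control ganglion cells pooling the
#' bipolar response, and an excitatory/inhibitory cortical column pair: the
#' ganglion firing rates feed the excitatory population through
#' retino-cortical rate synapses (density ratio 400/4000 per mm^2), the
#' excitatory population spreads laterally through delayed Gaussian
#' rate coupling (conduction-velocity delays) onto both populations, and
#' the inhibitory population feeds back one-to-one with negative weight.
#' There is no thalamus stage.
#'
#' @param nx,ny retinal and cortical grid size (default 8 x 8).
#' @param spacing retinal cell spacing, mm.
#' @param bar_speed_px bar speed in px/s of the 32 px wide stimulus frame.
#' @param t_end,dt duration and step, s.
#' @param drive_gain gray-level to OPL-drive gain (mV per filtered gray
#'   unit).
#' @param params per-type parameter overrides.
#' @return list with \code{graph}, \code{session} and \code{stimulus}.
#' @export
build_retino_cortical <- function(nx = 8, ny = 8, spacing = 0.05,
                                  bar_speed_px = 24, t_end = 1.2, dt = 1e-3,
                                  drive_gain = 0.1, params = list()) {
  bip <- layer_spec("bipolar", "bipolar_gain_control", nx, ny,
                    spacing = spacing, z = 0)
  ama <- layer_spec("amacrine", "linear_cell", nx, ny, spacing = spacing,
                    z = 0.05)
  rgc <- layer_spec("ganglion", "ganglion_gain_control", nx, ny,
                    spacing = spacing, z = 0.1)
  cx_e <- layer_spec("cortex_exc", "cortical_excitatory", nx, ny,
                     spacing = spacing, z = 1)
  cx_i <- layer_spec("cortex_inh", "cortical_inhibitory", nx, ny,
                     spacing = spacing, z = 1.05)

  inh <- function(e) { e$weight <- -e$weight; e }
  edges <- rbind(
    connect(bip, ama, "one_to_one", "rectified"),
    inh(connect(ama, bip, "one_to_one", "linear")),
    connect(bip, rgc, "one_to_one", "bipolar_pooling", weight_const = 20),
    inh(connect(ama, rgc, "one_to_one", "linear")),
    connect(rgc, cx_e, "one_to_one", "retino_cortical"),
    connect(cx_e, cx_e, "gaussian", "cortical_rate_delayed",
            sigma_p = 2 * spacing),
    connect(cx_e, cx_i, "gaussian", "cortical_rate_delayed",
            sigma_p = 2 * spacing),
    inh(connect(cx_i, cx_e, "one_to_one", "cortical_rate"))
  )

  graph <- sim_graph(
    layers = list(bip, ama, rgc, cx_e, cx_i),
    edges = edges,
    initial_values = list(
      bipolar = list(A_B = 0, V = -60),
      amacrine = list(V = -60),
      ganglion = list(V = -60, A_G = 0),
      cortex_exc = list(V_pop = 0),
      cortex_inh = list(V_pop = 0)
    )
  )
  # Gaussian lateral weights sum to ~1/spacing^2 per cell; scale the rate
  # coupling so the summed lateral gain is O(1) and the loop stays stable
  params <- modifyList(
    list(cortical_rate_delayed = list(w = 0.5 * spacing^2),
         retino_cortical = list(weight = 100)), params)
  field_px <- 32L
  stim_spec <- list(type = "moving_bar", width = 4, speed = bar_speed_px,
                    duration = t_end, fps = 50, size = c(field_px, field_px),
                    px_size = nx * spacing / field_px)
  session <- sim_session(
    graph = graph, params = params, worker = "visual_flow",
    stimulus = stim_spec,
    rf = list(sigma_c = 1.2 * spacing, sigma_s = 3 * spacing,
              w_c = 1, w_s = 0.5, tau_rf = 0.02, n_rf = 1),
    solver = "rk4", dt = dt, t_end = t_end, dt_record = max(dt, 5e-3),
    record = list(list(layer = "bipolar", var = "V", cells = "all"),
                  list(layer = "amacrine", var = "V", cells = "all"),
                  list(layer = "ganglion", var = "V", cells = "all"),
                  list(layer = "cortex_exc", var = "V_pop", cells = "all"),
                  list(layer = "cortex_inh", var = "V_pop", cells = "all")),
    drive_gain = drive_gain, drive_layers = "bipolar"
  )
  list(graph = graph, session = session, stimulus = stim_spec)
}

#' Amari-Wilson-Cowan scenario
#'
#' One layer of voltage units
#' \code{dV_i/dt = -V_i/tau + sum_j J_ij f(V_j) + H_ext} with
#' \code{f(x) = (1 + erf(g x / sqrt(2))) / 2} and Gaussian pooling weights
#' \code{J_ij} (the coupling synapse multiplies the Gaussian geometric
#' weight by the scale \code{J0}, mV/s). \code{H_ext} enters as a constant
#' drive; with \code{g = 0} the coupling freezes at \code{J/2} and the
#' network relaxes linearly to \code{V* = tau (J rowsum / 2 + H_ext)}.
#'
#' @param nx,ny lattice size (default 16 x 16).
#' @param tau integration time, s.
#' @param g sigmoid gain, 1/mV.
#' @param sigma_p Gaussian pooling width, mm.
#' @param J0 coupling scale multiplying the Gaussian weights, mV/s.
#' @param H_ext constant external drive, mV/s.
#' @param spacing cell spacing, mm.
#' @param t_end,dt duration and step, s.
#' @param V0 initial voltage, mV (scalar or per-cell).
#' @return list with \code{graph} and \code{session}.
#' @export
build_awc <- function(nx = 16, ny = 16, tau = 0.05, g = 1, sigma_p = 0.1,
                      J0 = 1, H_ext = 100, spacing = 0.05,
                      t_end = 2, dt = 1e-3, V0 = 0) {
  awc <- layer_spec("awc", "awc_cell", nx, ny, spacing = spacing, z = 0)
  edges <- connect(awc, awc, "gaussian", "awc_coupling", sigma_p = sigma_p)
  graph <- sim_graph(
    layers = list(awc), edges = edges,
    initial_values = list(awc = list(V = V0))
  )
  session <- sim_session(
    graph = graph,
    params = list(awc_cell = list(tau = tau, g = g, H_bias = H_ext),
                  awc_coupling = list(w = J0)),
    worker = "none", solver = "rk4", dt = dt, t_end = t_end,
    dt_record = max(dt, 5e-3),
    record = list(list(layer = "awc", var = "V", cells = "all"))
  )
  list(graph = graph, session = session)
}
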