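# shared fixtures built in code

the_registry <- model_registry()

# a one-layer, n-cell linear-cell graph with optional edges
linear_graph <- function(n = 1, edges = NULL, V0 = -50, tau = 0.05,
                         E_L = -60) {
  g <- sim_graph(
    layers = list(layer_spec("L", "linear_cell", n, 1)),
    edges = if (is.null(edges)) empty_edges_df() else edges,
    initial_values = list(L = list(V = rep(V0, length.out = n)))
  )
  attr(g, "tau") <- tau
  g
}

empty_edges_df <- function() {
  data.frame(pre_layer = character(0), pre_index = integer(0),
             post_layer = character(0), post_index = integer(0),
             synapse_type = character(0), weight = numeric(0),
             delay_steps = integer(0))
}

edge_df <- function(pre_layer, pre_index, post_layer, post_index,
                    synapse_type, weight = 1, delay_steps = 0L) {
  data.frame(pre_layer = pre_layer, pre_index = as.integer(pre_index),
             post_layer = post_layer, post_index = as.integer(post_index),
             synapse_type = synapse_type, weight = weight,
             delay_steps = as.integer(delay_steps))
}

# random state/parameter points for a cell definition; parameters are
# perturbed around their defaults, states drawn in plausible ranges
random_cell_points <- function(def, n_points = 100, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_points), function(i) {
    state <- lapply(setNames(nm = names(def$state_vars)), function(v) {
      if (v %in% c("V", "V_pop")) stats::runif(1, -80, 20)
      else if (v %in% c("m", "h", "n", "N", "R", "S")) stats::runif(1, 0, 1)
      else stats::runif(1, 0, 5)  # concentrations / activities
    })
    params <- lapply(def$params, function(p) p * stats::runif(1, 0.8, 1.2) +
                       ifelse(p == 0, stats::runif(1, -0.5, 0.5), 0))
    inputs <- list(ext = stats::runif(1, -50, 50),
                   I_syn = stats::runif(1, -100, 100),
                   V_syn = stats::runif(1, -100, 100),
                   FR_syn = stats::runif(1, 0, 50))
    list(state = state, params = params, inputs = inputs)
  })
}

rel_diff <- function(a, b) {
  abs(a - b) / pmax(abs(a), abs(b), 1e-8)
}
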