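# Layer lattices, the six connectivity generators, Gaussian weight profiles,
# and graph/parameter JSON round-trip.

#' Define a cell layer on a 2-D grid
#'
#' Cells of one type arranged row-major on an \code{nx} by \code{ny} grid
#' with uniform spacing. All cells of a layer share the vertical coordinate
#' \code{z} and (at simulation time) the same parameter set. Cell indices
#' are 0-based from the origin corner in the on-disk format and 1-based
#' inside R.
#'
#' @param name layer name (unique within a graph).
#' @param cell_type cell type name (resolved against a registry).
#' @param nx,ny grid counts (>= 1).
#' @param spacing inter-cell distance (> 0), in \code{modality} units.
#' @param modality one of \code{"mm"}, \code{"degrees"}, \code{"pixels"}.
#' @param origin length-2 numeric, position of cell 0.
#' @param z vertical layer coordinate.
#' @return object of class \code{"layer_spec"}.
#' @export
layer_spec <- function(name, cell_type, nx, ny, spacing = 0.1,
                       modality = c("mm", "degrees", "pixels"),
                       origin = c(0, 0), z = 0) {
  modality <- match.arg(modality)
  stopifnot(nx >= 1, ny >= 1, spacing > 0, length(origin) == 2)
  structure(
    list(name = name, cell_type = cell_type, nx = as.integer(nx),
         ny = as.integer(ny), spacing = spacing, modality = modality,
         origin = as.numeric(origin), z = z),
    class = "layer_spec"
  )
}

#' Number of cells in a layer
#' @param layer a [layer_spec()].
#' @return integer.
#' @export
layer_size <- function(layer) layer$nx * layer$ny

#' Cell positions on the layer grid
#'
#' Row-major: index i (1-based) maps to column \code{(i-1) \%\% nx} and row
#' \code{(i-1) \%/\% nx}; position is \code{origin + spacing * (col, row)}.
#'
#' @param layer a [layer_spec()].
#' @param index 1-based cell indices (default all).
#' @return matrix with columns \code{x}, \code{y}.
#' @export
cell_position <- function(layer, index = seq_len(layer_size(layer))) {
  if (any(index < 1L | index > layer_size(layer))) {
    stop(validation_error(sprintf("cell index out of range for layer '%s'",
                                  layer$name)))
  }
  i0 <- index - 1L
  cbind(x = layer$origin[1] + layer$spacing * (i0 %% layer$nx),
        y = layer$origin[2] + layer$spacing * (i0 %/% layer$nx))
}

#' Planar Euclidean distance between cells
#'
#' Distance is measured in the common (x, y) frame; the vertical separation
#' between layers is ignored, so a cell and its zero-distance partner in
#' another layer are at distance 0.
#'
#' @param pos_a,pos_b two-column position matrices (recycled rowwise if one
#'   has a single row).
#' @return numeric vector of distances.
#' @export
euclidean_distance <- function(pos_a, pos_b) {
  pos_a <- rbind(pos_a); pos_b <- rbind(pos_b)
  unname(sqrt((pos_a[, 1] - pos_b[, 1])^2 + (pos_a[, 2] - pos_b[, 2])^2))
}

#' Gaussian connectivity weight
#'
#' \code{W = exp(-d^2 / (2 sigma_p^2)) / (2 pi sigma_p^2)}: the normalized
#' 2-D Gaussian profile, so summing W over a fine grid of partners
#' approximates \code{1 / spacing^2}.
#'
#' @param d distance (vectorized).
#' @param sigma_p Gaussian pooling width (> 0), same units as \code{d}.
#' @return weight.
#' @export
#' @examples
#' gaussian_weight(0, 1)  # 1/(2*pi)
gaussian_weight <- function(d, sigma_p) {
  stopifnot(sigma_p > 0)
  exp(-d^2 / (2 * sigma_p^2)) / (2 * pi * sigma_p^2)
}

.connect_kinds <- c("one_to_one", "nearest_neighbors", "neighbor_4_plus_1",
                    "radius", "gaussian", "fully_connected")

#' Generate edges between (or within) layers
#'
#' The six lattice connectivity kinds:
#' \describe{
#'   \item{one_to_one}{each cell to the zero-distance cell of the other
#'     layer; requires equal grid counts.}
#'   \item{nearest_neighbors}{each cell to every cell at the minimal
#'     strictly-positive distance (4 in a lattice interior; 2-3 at
#'     boundaries; ties connect to all tied cells).}
#'   \item{neighbor_4_plus_1}{nearest neighbors plus the zero-distance cell;
#'     requires equal grid counts.}
#'   \item{radius}{all cells with \code{0 < d <= radius}, constant weight.}
#'   \item{gaussian}{weights from [gaussian_weight()], including d = 0;
#'     truncated at \code{d > trunc_sigma * sigma_p}.}
#'   \item{fully_connected}{all cells of the other layer, constant weight.}
#' }
#' For intra-layer use pass the same layer twice; self-edges (d = 0 within
#' one layer) are excluded except where a kind explicitly includes the
#' zero-distance cell across layers.
#'
#' @param pre_layer,post_layer [layer_spec()] objects.
#' @param kind one of the six kinds above.
#' @param synapse_type synapse type name stamped on the edges.
#' @param radius radius for \code{kind = "radius"}.
#' @param sigma_p Gaussian width for \code{kind = "gaussian"}.
#' @param weight_const constant weight for the non-Gaussian kinds.
#' @param trunc_sigma truncation radius for Gaussian connectivity, in units
#'   of \code{sigma_p} (default 4; weights beyond are below
#'   \code{exp(-8)/(2 pi sigma_p^2)}).
#' @param delay_steps integer delay stamped on the edges (default 0; the
#'   engine recomputes delays from distance for delayed synapse types).
#' @return data.frame of edges: \code{pre_layer}, \code{pre_index},
#'   \code{post_layer}, \code{post_index} (1-based), \code{synapse_type},
#'   \code{weight}, \code{delay_steps}.
#' @export
connect <- function(pre_layer, post_layer, kind, synapse_type,
                    radius = NULL, sigma_p = NULL, weight_const = 1,
                    trunc_sigma = 4, delay_steps = 0L) {
  kind <- match.arg(kind, .connect_kinds)
  intra <- identical(pre_layer$name, post_layer$name)
  if (kind %in% c("one_to_one", "neighbor_4_plus_1") &&
      (pre_layer$nx != post_layer$nx || pre_layer$ny != post_layer$ny)) {
    stop(validation_error(sprintf(
      "connectivity '%s' requires layers with the same number of cells", kind)))
  }
  n_pre <- layer_size(pre_layer)
  n_post <- layer_size(post_layer)
  pos_pre <- cell_position(pre_layer)
  pos_post <- cell_position(post_layer)

  pre_idx <- integer(0); post_idx <- integer(0); w <- numeric(0)

  add <- function(pi, qi, wi) {
    pre_idx <<- c(pre_idx, pi); post_idx <<- c(post_idx, qi)
    w <<- c(w, wi)
  }

  if (kind == "one_to_one") {
    add(seq_len(n_pre), seq_len(n_post), rep(weight_const, n_pre))
  } else if (kind == "fully_connected") {
    add(rep(seq_len(n_pre), each = n_post),
        rep(seq_len(n_post), times = n_pre),
        rep(weight_const, n_pre * n_post))
  } else {
    for (i in seq_len(n_pre)) {
      d <- euclidean_distance(pos_pre[i, , drop = FALSE], pos_post)
      # nearest/radius kinds never target the d = 0 cell of the own layer;
      # gaussian keeps it (the profile includes d = 0, a self-edge
      # intra-layer)
      if (intra && kind != "gaussian") d[i] <- NA
      if (kind %in% c("nearest_neighbors", "neighbor_4_plus_1")) {
        dpos <- d[!is.na(d) & d > 0]
        if (!length(dpos)) next
        dmin <- min(dpos)
        sel <- which(!is.na(d) & d > 0 & abs(d - dmin) < 1e-9 * max(dmin, 1))
        if (kind == "neighbor_4_plus_1") {
          sel <- c(sel, which(!is.na(d) & d == 0))
        }
        add(rep(i, length(sel)), sel, rep(weight_const, length(sel)))
      } else if (kind == "radius") {
        if (is.null(radius)) {
          stop(validation_error("radius connectivity needs 'radius'"))
        }
        sel <- which(!is.na(d) & d > 0 & d <= radius)
        add(rep(i, length(sel)), sel, rep(weight_const, length(sel)))
      } else if (kind == "gaussian") {
        if (is.null(sigma_p)) {
          stop(validation_error("gaussian connectivity needs 'sigma_p'"))
        }
        sel <- which(!is.na(d) & d <= trunc_sigma * sigma_p)
        add(rep(i, length(sel)), sel, gaussian_weight(d[sel], sigma_p))
      }
    }
  }

  data.frame(
    pre_layer = rep(pre_layer$name, length(pre_idx)),
    pre_index = as.integer(pre_idx),
    post_layer = rep(post_layer$name, length(pre_idx)),
    post_index = as.integer(post_idx),
    synapse_type = rep(synapse_type, length(pre_idx)),
    weight = w,
    delay_steps = as.integer(rep(delay_steps, length.out = length(pre_idx)))
  )
}

empty_edges <- function() {
  data.frame(pre_layer = character(0), pre_index = integer(0),
             post_layer = character(0), post_index = integer(0),
             synapse_type = character(0), weight = numeric(0),
             delay_steps = integer(0))
}

#' Assemble a simulation graph
#'
#' @param layers list of [layer_spec()] (names taken from the specs).
#' @param edges data.frame as produced by [connect()] (rbind several calls
#'   for multiple connectivities).
#' @param initial_values named list: layer name -> named list mapping state
#'   variable to either a scalar (shared) or a vector of per-cell values.
#' @return object of class \code{"sim_graph"}.
#' @export
sim_graph <- function(layers, edges = empty_edges(), initial_values = list()) {
  names(layers) <- vapply(layers, `[[`, "", "name")
  g <- structure(list(layers = layers, edges = edges,
                      initial_values = initial_values),
                 class = "sim_graph")
  g
}

#' Validate a graph against a registry
#'
#' Checks: edge indices in range, all cell and synapse types exist, each
#' edge's synapse output kind matches an input slot of the post-synaptic
#' cell type, pre-synaptic cell types expose the outputs the rule reads, and
#' initial values cover every state variable with length 1 or layer size.
#'
#' @param graph a [sim_graph()].
#' @param registry a [model_registry()].
#' @return TRUE invisibly; raises a \code{retinet_validation_error}
#'   otherwise.
#' @export
validate_graph <- function(graph, registry) {
  slot_of <- c(current = "synaptic_current",
               voltage_rate = "synaptic_voltage_rate",
               firing_rate = "synaptic_firing_rate")
  for (ly in graph$layers) {
    def <- get_type(registry, ly$cell_type)
    if (!identical(def$kind, "cell")) {
      stop(validation_error(sprintf("layer '%s': '%s' is not a cell type",
                                    ly$name, ly$cell_type)))
    }
    iv <- graph$initial_values[[ly$name]]
    missing_iv <- setdiff(names(def$state_vars), names(iv))
    if (length(missing_iv)) {
      stop(validation_error(sprintf(
        "layer '%s': missing initial values for %s",
        ly$name, paste(missing_iv, collapse = ",")), fields = missing_iv))
    }
    for (v in names(iv)) {
      if (!length(iv[[v]]) %in% c(1L, layer_size(ly))) {
        stop(validation_error(sprintf(
          "layer '%s': initial values for '%s' must have length 1 or %d",
          ly$name, v, layer_size(ly))))
      }
    }
  }
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    pre <- graph$layers[[e$pre_layer[k]]]
    post <- graph$layers[[e$post_layer[k]]]
    if (is.null(pre) || is.null(post)) {
      stop(validation_error(sprintf("edge %d references unknown layer", k)))
    }
    if (e$pre_index[k] < 1L || e$pre_index[k] > layer_size(pre) ||
        e$post_index[k] < 1L || e$post_index[k] > layer_size(post)) {
      stop(validation_error(sprintf("edge %d has an out-of-range index", k)))
    }
  }
  for (st in unique(e$synapse_type)) {
    sdef <- get_type(registry, st)
    if (!identical(sdef$kind, "synapse")) {
      stop(validation_error(sprintf("'%s' is not a synapse type", st)))
    }
    sub <- e[e$synapse_type == st, ]
    for (pl in unique(sub$pre_layer)) {
      cdef <- get_type(registry, graph$layers[[pl]]$cell_type)
      lacks <- setdiff(sdef$pre_refs, names(cdef$outputs))
      if (length(lacks)) {
        stop(validation_error(sprintf(
          "synapse '%s' from layer '%s': cell type '%s' lacks output(s) %s",
          st, pl, cdef$name, paste(lacks, collapse = ","))))
      }
    }
    for (pl in unique(sub$post_layer)) {
      cdef <- get_type(registry, graph$layers[[pl]]$cell_type)
      if (!slot_of[[sdef$output_kind]] %in% cdef$input_slots) {
        stop(validation_error(sprintf(
          "synapse '%s' feeds slot '%s' but cell type '%s' (layer '%s') does not accept it",
          st, slot_of[[sdef$output_kind]], cdef$name, pl)))
      }
      lacks <- setdiff(sdef$post_refs, names(cdef$outputs))
      if (length(lacks)) {
        stop(validation_error(sprintf(
          "synapse '%s' onto layer '%s': cell type '%s' lacks output(s) %s",
          st, pl, cdef$name, paste(lacks, collapse = ","))))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.sim_graph <- function(x, ...) {
  cat(sprintf("<simulation graph> %d layers, %d cells, %d edges\n",
              length(x$layers),
              sum(vapply(x$layers, layer_size, 0L)),
              nrow(x$edges)))
  for (ly in x$layers) {
    cat(sprintf("  %s: %s %dx%d (spacing %g %s, z=%g)\n", ly$name,
                ly$cell_type, ly$nx, ly$ny, ly$spacing, ly$modality, ly$z))
  }
  invisible(x)
}

#' Save / load a graph as JSON
#'
#' The file stores the content of the original tool's graph file re-expressed
#' as documented JSON: layers with cell type and grid geometry, edges with
#' 0-based indices, and per-layer initial values. Round-trip is lossless.
#'
#' @param graph a [sim_graph()].
#' @param path destination file.
#' @return \code{path} invisibly (for \code{save_graph}); a [sim_graph()]
#'   (for \code{load_graph}).
#' @export
save_graph <- function(graph, path) {
  e <- graph$edges
  j <- list(
    layers = lapply(unname(graph$layers), function(ly)
      list(name = ly$name, cell_type = ly$cell_type, nx = ly$nx, ny = ly$ny,
           spacing = ly$spacing, modality = ly$modality,
           origin = ly$origin, z = ly$z)),
    edges = list(
      pre_layer = e$pre_layer, pre_index = e$pre_index - 1L,
      post_layer = e$post_layer, post_index = e$post_index - 1L,
      synapse_type = e$synapse_type, weight = e$weight,
      delay_steps = e$delay_steps
    ),
    initial_values = graph$initial_values
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  if (!file.exists(path)) {
    stop(validation_error(sprintf("graph file '%s' does not exist", path)))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("layers", "edges", "initial_values")) {
    if (is.null(j[[field]])) {
      stop(validation_error(sprintf("graph file '%s' lacks '%s'", path, field),
                            fields = field))
    }
  }
  lys <- lapply(seq_len(nrow(j$layers)), function(i) {
    r <- j$layers[i, ]
    layer_spec(r$name, r$cell_type, r$nx, r$ny, r$spacing, r$modality,
               unlist(r$origin), r$z)
  })
  ed <- j$edges
  edges <- data.frame(
    pre_layer = as.character(ed$pre_layer),
    pre_index = as.integer(ed$pre_index) + 1L,
    post_layer = as.character(ed$post_layer),
    post_index = as.integer(ed$post_index) + 1L,
    synapse_type = as.character(ed$synapse_type),
    weight = as.numeric(ed$weight),
    delay_steps = as.integer(ed$delay_steps)
  )
  iv <- lapply(j$initial_values, function(l) lapply(l, as.numeric))
  sim_graph(lys, edges, iv)
}
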