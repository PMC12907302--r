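# Simulation engine: assembles the global ODE system from a graph and a
# registry, integrates it with explicit fixed-step solvers, manages delay
# buffers and external drives, and records selected variables.
#
# State layout: layers are concatenated in graph order; within a layer the
# flat vector holds variable-major blocks (var 1 for cells 1..n, then var 2,
# ...). The slot map (layer, cell, var) -> index is a bijection.

integration_error <- function(msg, t = NA_real_, where = NULL) {
  structure(
    class = c("retinet_integration_error", "retinet_error", "error",
              "condition"),
    list(message = msg, call = sys.call(-1), t = t, where = where)
  )
}

.slot_of_kind <- c(current = "I_syn", voltage_rate = "V_syn",
                   firing_rate = "FR_syn")

#' Assemble the global ODE system
#'
#' Validates the graph against the registry, merges parameter overrides,
#' recomputes conduction delays for delayed synapse types from the 2-D
#' pre-post distances, groups edges for vectorized evaluation, precomputes
#' the external drive (visual-flow receptive-field response, prosthesis tile
#' averages, or none) on the \code{dt} grid, and returns a model whose
#' derivative is a pure function of (t, state, delay buffers).
#'
#' @param graph a [sim_graph()].
#' @param registry a [model_registry()].
#' @param dt integration step, s.
#' @param t_end simulated duration, s.
#' @param worker input mode: \code{"none"}, \code{"visual_flow"} or
#'   \code{"prosthesis"}.
#' @param stim a [stimulus()] (required for the visual workers).
#' @param rf a [receptive_field()] (visual_flow worker).
#' @param drive_gain scalar gain applied to the worker drive before it
#'   enters the cells' external slot.
#' @param drive_layers layer names receiving the drive; default every layer
#'   whose cell type has an \code{external} input slot.
#' @param params named list of per-type parameter overrides, e.g.
#'   \code{list(linear_cell = list(tau = 0.1))}.
#' @param use_reference use the hand-coded builtin vector fields instead of
#'   the compiled declarative ones where available (both must agree; the
#'   compiled path is the default).
#' @return object of class \code{"sim_model"}.
#' @export
assemble <- function(graph, registry, dt, t_end,
                     worker = c("none", "visual_flow", "prosthesis"),
                     stim = NULL, rf = NULL, drive_gain = 1,
                     drive_layers = NULL, params = list(),
                     use_reference = FALSE) {
  worker <- match.arg(worker)
  validate_graph(graph, registry)
  if (worker == "none" && !is.null(stim)) {
    warning("worker 'none': the configured stimulus is ignored")
    stim <- NULL
  }
  if (worker != "none" && is.null(stim)) {
    stop(validation_error(sprintf("worker '%s' requires a stimulus", worker)))
  }

  lnames <- names(graph$layers)
  layers <- list()
  offset <- 0L
  for (ln in lnames) {
    ly <- graph$layers[[ln]]
    def <- get_type(registry, ly$cell_type)
    p <- modifyList(as.list(def$params), params[[ly$cell_type]] %||% list())
    p <- modifyList(p, params[[ln]] %||% list())
    n <- layer_size(ly)
    vars <- names(def$state_vars)
    rhs_fun <- if (use_reference && !is.null(.builtin_cell_rhs[[def$name]])) {
      .builtin_cell_rhs[[def$name]]
    } else {
      cell_rhs_fun(def)
    }
    out_fun <- if (use_reference &&
                   !is.null(.builtin_cell_outputs[[def$name]])) {
      .builtin_cell_outputs[[def$name]]
    } else {
      cell_outputs_fun(def)
    }
    layers[[ln]] <- list(
      name = ln, spec = ly, def = def, params = p, n = n, vars = vars,
      offset = offset, rhs_fun = rhs_fun, out_fun = out_fun,
      slots = intersect(c("external", "synaptic_current",
                          "synaptic_voltage_rate", "synaptic_firing_rate"),
                        def$input_slots)
    )
    offset <- offset + n * length(vars)
  }
  n_state <- offset

  # --- edge groups ---------------------------------------------------------
  e <- graph$edges
  groups <- list()
  if (nrow(e)) {
    key <- paste(e$synapse_type, e$pre_layer, e$post_layer, sep = "\r")
    for (k in unique(key)) {
      sub <- e[key == k, , drop = FALSE]
      sdef <- get_type(registry, sub$synapse_type[1])
      sp <- modifyList(as.list(sdef$params),
                       params[[sdef$name]] %||% list())
      pre_ln <- sub$pre_layer[1]
      post_ln <- sub$post_layer[1]
      delay <- if (sdef$delayed) {
        d <- euclidean_distance(
          cell_position(graph$layers[[pre_ln]], sub$pre_index),
          cell_position(graph$layers[[post_ln]], sub$post_index))
        synaptic_delay(d, sp$conduction_velocity, dt)
      } else {
        as.integer(sub$delay_steps)
      }
      groups[[length(groups) + 1L]] <- list(
        synapse = sdef, params = sp, rule = synapse_rule_fun(sdef),
        pre_layer = pre_ln, post_layer = post_ln,
        pre_idx = sub$pre_index, post_idx = sub$post_index,
        w = sub$weight, delay = delay,
        slot = .slot_of_kind[[sdef$output_kind]]
      )
    }
  }

  # delay buffers needed: (pre layer, output name) -> max delay
  buf_req <- list()
  for (g in groups) {
    if (any(g$delay > 0L)) {
      for (ref in g$synapse$pre_refs) {
        bk <- paste(g$pre_layer, ref, sep = "\r")
        buf_req[[bk]] <- max(buf_req[[bk]] %||% 0L, max(g$delay))
      }
    }
  }

  # --- external drive ------------------------------------------------------
  if (is.null(drive_layers)) {
    drive_layers <- lnames[vapply(layers, function(l)
      "external" %in% l$slots, TRUE)]
  }
  drive <- list()
  if (worker == "visual_flow") {
    if (is.null(rf)) {
      stop(validation_error("worker 'visual_flow' requires a receptive field"))
    }
    for (ln in drive_layers) {
      pos <- cell_position(graph$layers[[ln]])
      resp <- dog_response(stim, rf, pos, dt, t_end)
      drive[[ln]] <- drive_gain * resp$drive
    }
  } else if (worker == "prosthesis") {
    for (ln in drive_layers) {
      resp <- prosthesis_input(stim, graph$layers[[ln]], gain = drive_gain,
                               dt = dt, t_end = t_end)
      drive[[ln]] <- resp$drive
    }
  }

  structure(
    list(graph = graph, layers = layers, groups = groups, buf_req = buf_req,
         n_state = n_state, dt = dt, t_end = t_end, worker = worker,
         drive = drive),
    class = "sim_model"
  )
}

#' @export
print.sim_model <- function(x, ...) {
  cat(sprintf(
    "<simulation model> %d state variables, %d layers, %d edge groups, worker '%s'\n",
    x$n_state, length(x$layers), length(x$groups), x$worker))
  invisible(x)
}

#' Flat-state slot indices for a layer variable
#' @param model a [assemble()]d model.
#' @param layer layer name.
#' @param var state-variable name.
#' @return integer indices into the flat state vector (one per cell).
#' @export
state_slots <- function(model, layer, var) {
  l <- model$layers[[layer]]
  if (is.null(l)) stop(validation_error(sprintf("unknown layer '%s'", layer)))
  vi <- match(var, l$vars)
  if (is.na(vi)) {
    stop(validation_error(sprintf("layer '%s' has no state variable '%s'",
                                  layer, var)))
  }
  l$offset + (vi - 1L) * l$n + seq_len(l$n)
}

.layer_state <- function(model, X) {
  out <- list()
  for (l in model$layers) {
    nv <- length(l$vars)
    s <- list()
    for (vi in seq_len(nv)) {
      s[[l$vars[vi]]] <- X[l$offset + (vi - 1L) * l$n + seq_len(l$n)]
    }
    out[[l$name]] <- s
  }
  out
}

.flatten_derivs <- function(model, dlist) {
  dX <- numeric(model$n_state)
  for (l in model$layers) {
    d <- dlist[[l$name]]
    for (vi in seq_along(l$vars)) {
      dX[l$offset + (vi - 1L) * l$n + seq_len(l$n)] <- d[[l$vars[vi]]]
    }
  }
  dX
}

# accumulate per-edge values onto post cells
.scatter_add <- function(acc, vals, post_idx) {
  s <- rowsum(vals, post_idx, reorder = FALSE)
  acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1L]
  acc
}

#' Initialize the simulation state
#'
#' Builds the flat state vector from the graph's initial values and
#' pre-fills every required delay buffer with the corresponding layer
#' output at t = 0.
#'
#' @param model a [assemble()]d model.
#' @return object of class \code{"sim_state"} with fields \code{t},
#'   \code{X}, \code{buffers}.
#' @export
init_state <- function(model) {
  X <- numeric(model$n_state)
  for (l in model$layers) {
    iv <- model$graph$initial_values[[l$name]]
    for (vi in seq_along(l$vars)) {
      v <- iv[[l$vars[vi]]]
      X[l$offset + (vi - 1L) * l$n + seq_len(l$n)] <- rep(v, length.out = l$n)
    }
  }
  st <- .layer_state(model, X)
  buffers <- list()
  for (bk in names(model$buf_req)) {
    parts <- strsplit(bk, "\r", fixed = TRUE)[[1]]
    l <- model$layers[[parts[1]]]
    out0 <- l$out_fun(st[[parts[1]]], l$params)[[parts[2]]]
    buffers[[bk]] <- delay_buffer(out0, model$buf_req[[bk]])
  }
  structure(list(t = 0, X = X, buffers = buffers), class = "sim_state")
}

# derivative of the assembled system at (t, X) given frozen delay buffers
model_deriv <- function(model, t, X, buffers) {
  st <- .layer_state(model, X)
  outs <- list()
  for (l in model$layers) outs[[l$name]] <- l$out_fun(st[[l$name]], l$params)

  inputs <- list()
  for (l in model$layers) {
    inp <- list(ext = 0, I_syn = 0, V_syn = 0, FR_syn = 0)
    dm <- model$drive[[l$name]]
    if (!is.null(dm)) {
      # zero-order hold on the dt grid
      inp$ext <- dm[min(floor(t / model$dt + 1e-9) + 1, nrow(dm)), ]
    }
    inputs[[l$name]] <- inp
  }

  for (g in model$groups) {
    post_out_full <- outs[[g$post_layer]]
    instant <- g$delay == 0L
    for (pass in c("now", "delayed")) {
      sel <- if (pass == "now") which(instant) else which(!instant)
      if (!length(sel)) next
      pre_gather <- list()
      if (pass == "now") {
        pre_out_full <- outs[[g$pre_layer]]
        for (ref in g$synapse$pre_refs) {
          pre_gather[[ref]] <- pre_out_full[[ref]][g$pre_idx[sel]]
        }
      } else {
        for (ref in g$synapse$pre_refs) {
          bk <- paste(g$pre_layer, ref, sep = "\r")
          pre_gather[[ref]] <- buffer_read(buffers[[bk]], g$pre_idx[sel],
                                           g$delay[sel])
        }
      }
      post_gather <- list()
      for (ref in g$synapse$post_refs) {
        post_gather[[ref]] <- post_out_full[[ref]][g$post_idx[sel]]
      }
      vals <- g$rule(pre_gather, post_gather, g$w[sel], g$params)
      acc <- inputs[[g$post_layer]][[g$slot]]
      if (length(acc) == 1L) acc <- rep(acc, model$layers[[g$post_layer]]$n)
      inputs[[g$post_layer]][[g$slot]] <-
        .scatter_add(acc, vals, g$post_idx[sel])
    }
  }

  dlist <- list()
  for (l in model$layers) {
    dlist[[l$name]] <- l$rhs_fun(st[[l$name]], l$params, inputs[[l$name]])
  }
  .flatten_derivs(model, dlist)
}

.solvers <- c("euler", "rk2", "rk4", "rk45")

.advance_X <- function(model, t, X, dt, solver, buffers) {
  f <- function(tt, x) model_deriv(model, tt, x, buffers)
  if (solver == "euler") {
    X + dt * f(t, X)
  } else if (solver == "rk2") { # midpoint
    k1 <- f(t, X)
    X + dt * f(t + dt / 2, X + dt / 2 * k1)
  } else if (solver == "rk4") {
    k1 <- f(t, X)
    k2 <- f(t + dt / 2, X + dt / 2 * k1)
    k3 <- f(t + dt / 2, X + dt / 2 * k2)
    k4 <- f(t + dt, X + dt * k3)
    X + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  } else if (solver == "rk45") {
    .rk45_span(f, t, X, dt)
  } else {
    stop(validation_error(sprintf("unknown solver '%s'", solver)))
  }
}

# Cash-Karp embedded RK45 with adaptive substeps across one fixed output
# interval [t, t+dt]; delays force the fixed reporting grid.
.rk45_span <- function(f, t, X, dt, rtol = 1e-6, atol = 1e-9) {
  t_endp <- t + dt
  h <- dt
  while (t < t_endp - 1e-12 * dt) {
    h <- min(h, t_endp - t)
    repeat {
      k1 <- f(t, X)
      k2 <- f(t + h / 5, X + h * k1 / 5)
      k3 <- f(t + 3 * h / 10, X + h * (3 * k1 + 9 * k2) / 40)
      k4 <- f(t + 3 * h / 5, X + h * (3 * k1 / 10 - 9 * k2 / 10 + 6 * k3 / 5))
      k5 <- f(t + h, X + h * (-11 * k1 / 54 + 5 * k2 / 2 - 70 * k3 / 27 +
                                35 * k4 / 27))
      k6 <- f(t + 7 * h / 8,
              X + h * (1631 * k1 / 55296 + 175 * k2 / 512 + 575 * k3 / 13824 +
                         44275 * k4 / 110592 + 253 * k5 / 4096))
      x5 <- X + h * (37 * k1 / 378 + 250 * k3 / 621 + 125 * k4 / 594 +
                       512 * k6 / 1771)
      x4 <- X + h * (2825 * k1 / 27648 + 18575 * k3 / 48384 +
                       13525 * k4 / 55296 + 277 * k5 / 14336 + k6 / 4)
      err <- max(abs(x5 - x4) / (atol + rtol * pmax(abs(X), abs(x5))))
      if (!is.finite(err)) {
        stop(integration_error("non-finite error estimate in rk45", t = t))
      }
      if (err <= 1) break
      h <- max(h * max(0.2, 0.9 * err^(-0.25)), 1e-6 * dt)
    }
    t <- t + h
    X <- x5
    if (err > 0) h <- h * min(5, 0.9 * err^(-0.2))
  }
  X
}

#' Advance the simulation by one step
#'
#' One explicit step of the chosen solver (\code{rk45} adapts substeps
#' internally but reports on the fixed \code{dt} grid, which the delay
#' buffers require). Delayed pre-synaptic samples are frozen at their
#' step-start values; instantaneous (0-step) edges see the stage states.
#' After the step the layer outputs are pushed into the delay buffers.
#'
#' @param model a [assemble()]d model.
#' @param state a [init_state()] (or previous step's) state.
#' @param dt step size, s (defaults to the model's dt).
#' @param solver one of \code{"euler"}, \code{"rk2"}, \code{"rk4"},
#'   \code{"rk45"}.
#' @return the state at t + dt.
#' @export
step <- function(model, state, dt = model$dt, solver = "rk4") {
  solver <- match.arg(solver, .solvers)
  X_new <- .advance_X(model, state$t, state$X, dt, solver, state$buffers)
  if (any(!is.finite(X_new))) {
    bad <- which(!is.finite(X_new))[1]
    where <- ""
    for (l in model$layers) {
      span <- l$n * length(l$vars)
      if (bad > l$offset && bad <= l$offset + span) {
        vi <- (bad - l$offset - 1L) %/% l$n + 1L
        ci <- (bad - l$offset - 1L) %% l$n + 1L
        where <- sprintf("layer '%s', cell %d, variable '%s'",
                         l$name, ci, l$vars[vi])
      }
    }
    stop(integration_error(
      sprintf("non-finite state at t = %g (%s); reduce dt or check the model",
              state$t + dt, where),
      t = state$t + dt, where = where))
  }
  state$X <- X_new
  state$t <- state$t + dt
  if (length(state$buffers)) {
    st <- .layer_state(model, X_new)
    for (bk in names(state$buffers)) {
      parts <- strsplit(bk, "\r", fixed = TRUE)[[1]]
      l <- model$layers[[parts[1]]]
      out_new <- l$out_fun(st[[parts[1]]], l$params)[[parts[2]]]
      state$buffers[[bk]] <- buffer_push(state$buffers[[bk]], out_new)
    }
  }
  state
}

#' Run an assembled model and record variables
#'
#' Fixed-step integration from t = 0 to \code{t_end}, recording the
#' requested (layer, cells, variable) series every \code{record_stride}
#' steps (including t = 0). Recording is non-invasive: it never feeds back
#' into the dynamics.
#'
#' @param model a [assemble()]d model.
#' @param solver solver name.
#' @param record list of record selections: each
#'   \code{list(layer =, var =, cells = "all" | integer vector)}. Default:
#'   every layer's first state variable, all cells.
#' @param record_stride record every this-many steps (default 1).
#' @return object of class \code{"sim_recording"}: a list of per-selection
#'   entries with \code{layer}, \code{var}, \code{cells}, \code{time},
#'   \code{values} (time x cells matrix).
#' @export
simulate_model <- function(model, solver = "rk4", record = NULL,
                           record_stride = 1L) {
  solver <- match.arg(solver, .solvers)
  if (is.null(record)) {
    record <- lapply(model$layers, function(l)
      list(layer = l$name, var = l$vars[1], cells = "all"))
  }
  record <- lapply(record, function(r) {
    cells <- r$cells %||% "all"
    if (identical(cells, "all")) {
      cells <- seq_len(model$layers[[r$layer]]$n)
    }
    list(layer = r$layer, var = r$var, cells = as.integer(cells),
         slots = state_slots(model, r$layer, r$var)[as.integer(cells)])
  })
  n_steps <- round(model$t_end / model$dt)
  rec_steps <- seq(0L, n_steps, by = record_stride)
  out <- lapply(record, function(r)
    matrix(NA_real_, length(rec_steps), length(r$cells)))
  times <- rec_steps * model$dt

  state <- init_state(model)
  ri <- 1L
  for (si in 0:n_steps) {
    if (si %in% rec_steps[ri] && ri <= length(rec_steps)) {
      for (j in seq_along(record)) {
        out[[j]][ri, ] <- state$X[record[[j]]$slots]
      }
      ri <- ri + 1L
    }
    if (si < n_steps) state <- step(model, state, model$dt, solver)
  }
  res <- Map(function(r, m) {
    list(layer = r$layer, var = r$var, cells = r$cells, time = times,
         values = m)
  }, record, out)
  names(res) <- vapply(record, function(r) paste0(r$layer, ".", r$var), "")
  structure(res, class = "sim_recording")
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf("<recording> %d series\n", length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %s: %d cells x %d samples (t in [%g, %g] s)\n", nm,
                length(x[[nm]]$cells), length(x[[nm]]$time),
                min(x[[nm]]$time), max(x[[nm]]$time)))
  }
  invisible(x)
}

#' Write a recording as CSV files
#'
#' One CSV per recorded series, columns \code{t} then \code{cell_<id>}.
#'
#' @param rec a [simulate_model()] recording.
#' @param dir destination directory (created).
#' @return character vector of written paths, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(rec)) {
    r <- rec[[nm]]
    df <- data.frame(t = r$time, r$values)
    names(df) <- c("t", paste0("cell_", r$cells))
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
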