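# Sessions: a declarative description of one batch run (graph + parameters +
# worker + solver + recording selection), loadable from JSON and executed by
# run().

#' Build a session configuration
#'
#' @param graph a [sim_graph()] or path to a graph JSON file.
#' @param params named list of per-type parameter overrides, or path to a
#'   parameters JSON file.
#' @param worker \code{"none"}, \code{"visual_flow"} or \code{"prosthesis"}.
#' @param stimulus a [stimulus()], path to a frame-stack directory, or a
#'   fixture spec \code{list(type = "moving_bar"|"full_field"|"grating",
#'   ...args)}.
#' @param rf a [receptive_field()] or a list of its arguments (visual_flow).
#' @param solver one of \code{"euler"}, \code{"rk2"}, \code{"rk4"},
#'   \code{"rk45"}.
#' @param dt integration step, s (> 0).
#' @param t_end simulated duration, s (>= dt).
#' @param dt_record recording period, s (default \code{dt}; must be a
#'   multiple of \code{dt}).
#' @param record list of selections \code{list(layer =, var =,
#'   cells = "all" | 1-based indices)}; default records every layer's first
#'   state variable.
#' @param drive_gain,drive_layers worker drive scaling and targets (see
#'   [assemble()]).
#' @param seed integer seed applied before the run (only scenario-builder
#'   jitter and user models consume randomness; the engine itself is
#'   deterministic).
#' @param output_dir if set, [run()] writes CSVs and a manifest there.
#' @return object of class \code{"sim_session"}.
#' @export
sim_session <- function(graph, params = list(), worker = "none",
                        stimulus = NULL, rf = NULL, solver = "rk4",
                        dt = 1e-4, t_end = 1, dt_record = NULL,
                        record = NULL, drive_gain = 1, drive_layers = NULL,
                        seed = NULL, output_dir = NULL) {
  worker <- match.arg(worker, c("none", "visual_flow", "prosthesis"))
  solver <- match.arg(solver, .solvers)
  if (!(dt > 0)) stop(validation_error("dt must be > 0"))
  if (!(t_end >= dt)) stop(validation_error("t_end must be >= dt"))
  dt_record <- dt_record %||% dt
  stride <- dt_record / dt
  if (abs(stride - round(stride)) > 1e-9) {
    stop(validation_error("dt_record must be an integer multiple of dt"))
  }
  structure(
    list(graph = graph, params = params, worker = worker,
         stimulus = stimulus, rf = rf, solver = solver, dt = dt,
         t_end = t_end, dt_record = dt_record, record = record,
         drive_gain = drive_gain, drive_layers = drive_layers, seed = seed,
         output_dir = output_dir),
    class = "sim_session"
  )
}

#' Load a session from JSON
#'
#' File fields mirror [sim_session()]; paths are resolved relative to the
#' session file; \code{record[].cells} are 0-based in the file (converted to
#' 1-based in R).
#'
#' @param path session JSON file.
#' @return a [sim_session()].
#' @export
load_session <- function(path) {
  if (!file.exists(path)) {
    stop(validation_error(sprintf("session file '%s' does not exist", path)))
  }
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  if (is.null(j$graph)) {
    stop(validation_error(sprintf("session '%s' lacks a graph", path)))
  }
  params <- j$params %||% list()
  if (is.character(params)) {
    params <- jsonlite::read_json(rel(params), simplifyVector = TRUE)
  }
  stim <- j$stimulus
  if (is.character(stim)) stim <- rel(stim)
  record <- lapply(j$record %||% list(), function(r) {
    cells <- r$cells %||% "all"
    if (!identical(cells, "all")) cells <- unlist(cells) + 1L
    list(layer = r$layer, var = r$var, cells = cells)
  })
  sim_session(
    graph = rel(j$graph), params = params, worker = j$worker %||% "none",
    stimulus = stim, rf = j$rf, solver = j$solver %||% "rk4",
    dt = j$dt %||% 1e-4, t_end = j$t_end %||% 1, dt_record = j$dt_record,
    record = if (length(record)) record else NULL,
    drive_gain = j$drive_gain %||% 1,
    drive_layers = unlist(j$drive_layers) %||% NULL,
    seed = j$seed, output_dir = if (!is.null(j$output_dir)) rel(j$output_dir)
  )
}

#' Save a session to JSON
#'
#' Only sessions whose graph/stimulus are referenced by path can be saved
#' (in-memory objects must be saved first with [save_graph()] /
#' [save_stimulus()]). \code{record[].cells} are written 0-based.
#'
#' @param session a [sim_session()].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
save_session <- function(session, path) {
  if (!is.character(session$graph)) {
    stop(validation_error("save_session: graph must be a file path"))
  }
  record <- lapply(session$record %||% list(), function(r) {
    cells <- r$cells %||% "all"
    if (!identical(cells, "all")) cells <- as.integer(cells) - 1L
    list(layer = r$layer, var = r$var, cells = cells)
  })
  j <- list(graph = session$graph, params = session$params,
            worker = session$worker, stimulus = session$stimulus,
            rf = if (!is.null(session$rf)) unclass(session$rf),
            solver = session$solver, dt = session$dt, t_end = session$t_end,
            dt_record = session$dt_record, record = record,
            drive_gain = session$drive_gain,
            drive_layers = session$drive_layers, seed = session$seed,
            output_dir = session$output_dir)
  j <- j[!vapply(j, is.null, TRUE)]
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.resolve_stimulus <- function(stim) {
  if (is.null(stim) || inherits(stim, "stimulus")) return(stim)
  if (is.character(stim)) return(load_stimulus(stim))
  if (is.list(stim)) {
    type <- stim$type %||% stop(validation_error("stimulus spec needs 'type'"))
    args <- stim[setdiff(names(stim), "type")]
    fn <- switch(type,
                 moving_bar = make_moving_bar,
                 full_field = make_full_field,
                 grating = make_grating,
                 stop(validation_error(sprintf("unknown stimulus type '%s'",
                                               type))))
    return(do.call(fn, args))
  }
  stop(validation_error("unrecognized stimulus specification"))
}

.resolve_rf <- function(rf) {
  if (is.null(rf) || inherits(rf, "receptive_field")) return(rf)
  do.call(receptive_field, rf)
}

#' Run a session
#'
#' Loads/validates all inputs, assembles the model, integrates it, and (if
#' \code{output_dir} is set) writes one CSV per recorded series plus a
#' \code{manifest.json} carrying the resolved configuration and seed.
#' Deterministic given (session, seed).
#'
#' @param session a [sim_session()] or path to a session JSON.
#' @param use_reference see [assemble()].
#' @return a recording (see [simulate_model()]).
#' @export
run <- function(session, use_reference = FALSE) {
  if (is.character(session)) session <- load_session(session)
  stopifnot(inherits(session, "sim_session"))
  if (!is.null(session$seed)) set.seed(session$seed)
  graph <- session$graph
  if (is.character(graph)) graph <- load_graph(graph)
  registry <- model_registry()
  stim <- .resolve_stimulus(session$stimulus)
  rf <- .resolve_rf(session$rf)
  model <- assemble(graph, registry, dt = session$dt, t_end = session$t_end,
                    worker = session$worker, stim = stim, rf = rf,
                    drive_gain = session$drive_gain,
                    drive_layers = session$drive_layers,
                    params = session$params, use_reference = use_reference)
  stride <- as.integer(round(session$dt_record / session$dt))
  rec <- simulate_model(model, solver = session$solver,
                        record = session$record, record_stride = stride)
  if (!is.null(session$output_dir)) {
    dir.create(session$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_recording(rec, session$output_dir)
    manifest <- list(
      package_version = as.character(utils::packageVersion("retinet")),
      worker = session$worker, solver = session$solver, dt = session$dt,
      t_end = session$t_end, dt_record = session$dt_record,
      seed = session$seed,
      graph = if (is.character(session$graph)) session$graph else "<inline>",
      n_layers = length(graph$layers), n_edges = nrow(graph$edges),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest,
                         file.path(session$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rec
}

#' Validate a session without running it
#'
#' Resolves the graph, parameters and (fixture) stimulus, and validates the
#' wiring against the registry.
#'
#' @param session a [sim_session()] or path.
#' @return TRUE invisibly; raises a validation error otherwise.
#' @export
validate_session <- function(session) {
  if (is.character(session)) session <- load_session(session)
  graph <- session$graph
  if (is.character(graph)) graph <- load_graph(graph)
  registry <- model_registry()
  validate_graph(graph, registry)
  if (session$worker != "none") {
    stim <- .resolve_stimulus(session$stimulus)
    if (is.null(stim)) {
      stop(validation_error(sprintf("worker '%s' requires a stimulus",
                                    session$worker)))
    }
    if (session$worker == "visual_flow") .resolve_rf(
      session$rf %||% stop(validation_error(
        "worker 'visual_flow' requires a receptive field")))
  }
  invisible(TRUE)
}
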