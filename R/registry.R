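# Declarative model registry: cell and synapse types are data (one JSON file
# per type), compiled at load time into evaluable vector fields. The shipped
# builtins mirror the hand-coded reference models in cells.R / synapses.R.

# canonical input-slot symbols usable inside cell equations
.input_slot_symbols <- c(
  external             = "ext",     # OPL drive (mV/s) or electrode current (pA)
  synaptic_current     = "I_syn",   # pA
  synaptic_voltage_rate = "V_syn",  # mV/s
  synaptic_firing_rate = "FR_syn"   # Hz
)

validation_error <- function(msg, fields = character(0)) {
  structure(
    class = c("retinet_validation_error", "retinet_error", "error",
              "condition"),
    list(message = msg, call = sys.call(-1), fields = fields)
  )
}

#' Construct (and compile) a cell type definition
#'
#' A cell type is a named ODE model: state variables, parameters with
#' defaults, input slots, optional auxiliary functions, one right-hand-side
#' expression per state variable, and named outputs readable by synapses.
#' All expressions are compiled on construction; an undeclared symbol or a
#' malformed equation fails here, not at simulation time.
#'
#' @param name identifier.
#' @param state_vars named character vector or list: state variable name ->
#'   unit string.
#' @param params named list of parameter defaults (plain numbers), or a list
#'   of lists with fields \code{default}, \code{unit}, \code{min}, \code{max}.
#' @param rhs named character vector: state variable -> equation text.
#' @param outputs named character vector: output name -> equation text over
#'   state vars, params and aux functions.
#' @param input_slots character subset of \code{c("external",
#'   "synaptic_current", "synaptic_voltage_rate", "synaptic_firing_rate")}.
#' @param aux_functions named character vector of helper expressions,
#'   evaluated in order before the rhs (later ones may reference earlier
#'   ones).
#' @param protected logical; protected definitions cannot be overwritten or
#'   deleted from a registry.
#' @return object of class \code{"cell_type_def"}.
#' @export
cell_type_def <- function(name, state_vars, params, rhs, outputs,
                          input_slots = character(0),
                          aux_functions = character(0),
                          protected = FALSE) {
  state_vars <- unlist(state_vars)
  if (is.null(names(state_vars)))
    state_vars <- setNames(rep("", length(state_vars)), state_vars)
  pdefs <- param_defaults(params)
  missing <- setdiff(names(state_vars), names(rhs))
  extra <- setdiff(names(rhs), names(state_vars))
  if (length(missing) || length(extra)) {
    stop(validation_error(sprintf(
      "cell type '%s': rhs must cover exactly the state variables (missing: %s; extra: %s)",
      name, paste(missing, collapse = ","), paste(extra, collapse = ",")),
      fields = c(missing, extra)))
  }
  bad_slots <- setdiff(input_slots, names(.input_slot_symbols))
  if (length(bad_slots)) {
    stop(validation_error(sprintf("cell type '%s': unknown input slots %s",
                                  name, paste(bad_slots, collapse = ",")),
                          fields = bad_slots))
  }
  slot_syms <- unname(.input_slot_symbols[input_slots])
  base_syms <- c(
    setNames(rep("state", length(state_vars)), names(state_vars)),
    setNames(rep("param", length(pdefs)), names(pdefs)),
    setNames(rep("input", length(slot_syms)), slot_syms)
  )
  aux <- list()
  syms <- base_syms
  for (an in names(aux_functions)) {
    aux[[an]] <- compile_expression(aux_functions[[an]], syms)
    syms <- c(syms, setNames("aux", an))
  }
  rhs_c <- lapply(rhs, compile_expression, symbols = syms)
  # outputs may use state, params and aux only (synapses read them without
  # knowing the cell's inputs)
  out_syms <- syms[!syms %in% "input"]
  outputs_c <- lapply(outputs, compile_expression, symbols = out_syms)
  structure(
    list(name = name, kind = "cell", state_vars = state_vars,
         params = pdefs, param_meta = param_meta(params),
         input_slots = input_slots, aux_functions = aux,
         rhs = rhs_c, outputs = outputs_c, protected = isTRUE(protected),
         src = list(aux_functions = as.list(aux_functions),
                    rhs = as.list(rhs), outputs = as.list(outputs))),
    class = "cell_type_def"
  )
}

param_defaults <- function(params) {
  vapply(params, function(p) {
    if (is.list(p)) as.numeric(p$default) else as.numeric(p)
  }, numeric(1))
}

param_meta <- function(params) {
  lapply(params, function(p) {
    if (is.list(p)) p[setdiff(names(p), "default")] else list()
  })
}

#' Construct (and compile) a synapse type definition
#'
#' A synapse type is a coupling rule producing one of three quantities:
#' a current (pA, summed into \code{I_syn}), a voltage rate (mV/s, summed
#' into \code{V_syn}) or a firing rate (Hz, summed into \code{FR_syn}).
#' The rule is an expression over the pre-synaptic cell's outputs (symbols
#' \code{<output>_pre}), the post-synaptic cell's outputs
#' (\code{<output>_post}), the geometric edge weight \code{w_edge}, and the
#' synapse parameters. A synapse is delayed exactly when its parameters
#' include one named \code{"conduction_velocity"} (mm/s).
#'
#' @param name identifier.
#' @param params named list of parameter defaults.
#' @param output_kind one of \code{"current"}, \code{"voltage_rate"},
#'   \code{"firing_rate"}.
#' @param rule equation text.
#' @param protected logical.
#' @return object of class \code{"synapse_type_def"} with logical field
#'   \code{delayed}.
#' @export
synapse_type_def <- function(name, params, output_kind, rule,
                             protected = FALSE) {
  output_kind <- match.arg(output_kind,
                           c("current", "voltage_rate", "firing_rate"))
  pdefs <- param_defaults(params)
  # pre/post output references are resolved at wiring time; declare every
  # *_pre / *_post symbol appearing in the rule
  tmp <- tryCatch(str2lang(normalize_equation_text(rule)), error = function(e) NULL)
  ref_syms <- if (is.null(tmp)) character(0) else all.names(tmp, functions = FALSE)
  ref_syms <- unique(ref_syms[grepl("_(pre|post)$", ref_syms)])
  ref_syms <- setdiff(ref_syms, names(pdefs))  # params shadow output refs
  syms <- c(
    setNames(rep("param", length(pdefs)), names(pdefs)),
    setNames(rep("edge", 1L), "w_edge"),
    setNames(rep("output_ref", length(ref_syms)), ref_syms)
  )
  rule_c <- compile_expression(rule, syms)
  structure(
    list(name = name, kind = "synapse", params = pdefs,
         param_meta = param_meta(params), output_kind = output_kind,
         rule = rule_c, pre_refs = sub("_pre$", "", grep("_pre$", ref_syms, value = TRUE)),
         post_refs = sub("_post$", "", grep("_post$", ref_syms, value = TRUE)),
         delayed = "conduction_velocity" %in% names(pdefs),
         protected = isTRUE(protected), src = list(rule = rule)),
    class = "synapse_type_def"
  )
}

#' @export
print.cell_type_def <- function(x, ...) {
  cat(sprintf("<cell type> %s%s\n", x$name,
              if (x$protected) " [protected]" else ""))
  cat("  state:  ", paste(names(x$state_vars), collapse = ", "), "\n")
  cat("  params: ", paste(names(x$params), collapse = ", "), "\n")
  cat("  inputs: ", paste(x$input_slots, collapse = ", "), "\n")
  cat("  outputs:", paste(names(x$outputs), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.synapse_type_def <- function(x, ...) {
  cat(sprintf("<synapse type> %s (%s)%s%s\n", x$name, x$output_kind,
              if (x$delayed) " [delayed]" else "",
              if (x$protected) " [protected]" else ""))
  cat("  rule:   ", x$rule$src, "\n")
  cat("  params: ", paste(names(x$params), collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# JSON round trip

#' Load a model definition from JSON
#'
#' Reads one model-definition file (schema: \code{name}, \code{kind} =
#' \code{"cell"}|\code{"synapse"}, \code{state_vars}, \code{params},
#' \code{input_slots}, \code{aux_functions}, \code{rhs}|\code{rule},
#' \code{outputs}, \code{output_kind}, \code{protected}) and compiles all
#' expressions. \code{save_type(load_type(path))} is content-identical.
#'
#' @param path path to a JSON file.
#' @return a [cell_type_def()] or [synapse_type_def()].
#' @export
load_type <- function(path) {
  if (!file.exists(path)) {
    stop(validation_error(sprintf("model file '%s' does not exist", path)))
  }
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  def_from_json(j, path = path)
}

def_from_json <- function(j, path = "<json>") {
  need <- function(field) {
    if (is.null(j[[field]])) {
      stop(validation_error(
        sprintf("model definition '%s' is missing field '%s'", path, field),
        fields = field))
    }
    j[[field]]
  }
  kind <- need("kind")
  name <- need("name")
  params <- lapply(j$params %||% list(), function(p) {
    if (is.list(p)) p else as.numeric(p)
  })
  if (identical(kind, "cell")) {
    sv <- need("state_vars")
    state_vars <- setNames(
      vapply(sv, function(s) if (is.list(s)) (s$unit %||% "") else "", ""),
      vapply(sv, function(s) if (is.list(s)) s$name else as.character(s), "")
    )
    cell_type_def(
      name = name, state_vars = state_vars, params = params,
      rhs = lapply(need("rhs"), as.character),
      outputs = lapply(j$outputs %||% list(), as.character),
      input_slots = unlist(j$input_slots %||% character(0)),
      aux_functions = lapply(j$aux_functions %||% list(), as.character),
      protected = isTRUE(j$protected)
    )
  } else if (identical(kind, "synapse")) {
    synapse_type_def(
      name = name, params = params,
      output_kind = need("output_kind"),
      rule = as.character(need("rule")),
      protected = isTRUE(j$protected)
    )
  } else {
    stop(validation_error(sprintf(
      "model definition '%s': kind must be 'cell' or 'synapse', got '%s'",
      path, kind), fields = "kind"))
  }
}

def_to_json <- function(def) {
  if (inherits(def, "cell_type_def")) {
    list(
      name = def$name, kind = "cell",
      state_vars = unname(Map(function(n, u) list(name = n, unit = u),
                              names(def$state_vars), unname(def$state_vars))),
      params = params_to_json(def),
      input_slots = as.list(def$input_slots),
      aux_functions = def$src$aux_functions,
      rhs = def$src$rhs,
      outputs = def$src$outputs,
      protected = def$protected
    )
  } else {
    list(
      name = def$name, kind = "synapse",
      params = params_to_json(def),
      output_kind = def$output_kind,
      rule = def$src$rule,
      protected = def$protected
    )
  }
}

params_to_json <- function(def) {
  out <- list()
  for (nm in names(def$params)) {
    meta <- def$param_meta[[nm]]
    if (length(meta)) {
      out[[nm]] <- c(list(default = unname(def$params[[nm]])), meta)
    } else {
      out[[nm]] <- unname(def$params[[nm]])
    }
  }
  out
}

#' Save a model definition to JSON
#' @param def a [cell_type_def()] or [synapse_type_def()].
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
save_type <- function(def, path) {
  jsonlite::write_json(def_to_json(def), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Registry

#' Create a model registry
#'
#' Loads the shipped builtin cell and synapse definitions (every pre-defined
#' model has a JSON twin under \code{inst/models/}) plus, optionally, a user
#' directory of additional definitions. The registry is an environment:
#' operations mutate it in place, as registries are session-scoped.
#'
#' @param user_dir optional directory of user model JSON files; new types are
#'   saved there and deleted from there.
#' @param builtins load the shipped definitions (default TRUE).
#' @return object of class \code{"model_registry"}.
#' @export
model_registry <- function(user_dir = NULL, builtins = TRUE) {
  reg <- new.env(parent = emptyenv())
  reg$types <- list()
  reg$files <- character(0)
  reg$user_dir <- user_dir
  class(reg) <- "model_registry"
  if (builtins) {
    dir <- system.file("models", package = "retinet")
    for (f in sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))) {
      def <- load_type(f)
      reg$types[[def$name]] <- def
      reg$files[[def$name]] <- f
    }
  }
  if (!is.null(user_dir) && dir.exists(user_dir)) {
    for (f in sort(list.files(user_dir, pattern = "\\.json$",
                              full.names = TRUE))) {
      def <- load_type(f)
      if (!is.null(reg$types[[def$name]]) && reg$types[[def$name]]$protected) {
        stop(protection_error(def$name))
      }
      reg$types[[def$name]] <- def
      reg$files[[def$name]] <- f
    }
  }
  reg
}

protection_error <- function(name) {
  structure(
    class = c("retinet_protection_error", "retinet_error", "error",
              "condition"),
    list(message = sprintf("model type '%s' is protected", name),
         call = sys.call(-1))
  )
}

notfound_error <- function(name) {
  structure(
    class = c("retinet_notfound_error", "retinet_error", "error", "condition"),
    list(message = sprintf("model type '%s' is not in the registry", name),
         call = sys.call(-1))
  )
}

#' Look up a model type
#' @param registry a [model_registry()].
#' @param name type name.
#' @return the definition.
#' @export
get_type <- function(registry, name) {
  def <- registry$types[[name]]
  if (is.null(def)) stop(notfound_error(name))
  def
}

#' Add (or overwrite) a model type in a registry
#'
#' Overwriting a protected definition is refused. If the registry has a user
#' directory, the definition is also saved there.
#'
#' @param registry a [model_registry()].
#' @param def a [cell_type_def()] or [synapse_type_def()].
#' @return the registry, invisibly.
#' @export
add_type <- function(registry, def) {
  old <- registry$types[[def$name]]
  if (!is.null(old) && old$protected) stop(protection_error(def$name))
  registry$types[[def$name]] <- def
  if (!is.null(registry$user_dir)) {
    dir.create(registry$user_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(registry$user_dir, paste0(def$name, ".json"))
    save_type(def, f)
    registry$files[[def$name]] <- f
  }
  invisible(registry)
}

#' Delete an unprotected model type
#'
#' Removes the type from the registry; if its file lives in the registry's
#' user directory, the file is deleted too (shipped builtin files are never
#' removed from the installed package).
#'
#' @param registry a [model_registry()].
#' @param name type name.
#' @return the registry, invisibly.
#' @export
delete_type <- function(registry, name) {
  def <- registry$types[[name]]
  if (is.null(def)) stop(notfound_error(name))
  if (def$protected) stop(protection_error(name))
  f <- registry$files[[name]]
  registry$types[[name]] <- NULL
  registry$files <- registry$files[names(registry$files) != name]
  if (!is.na(f) && length(f) && !is.null(registry$user_dir) &&
      startsWith(normalizePath(f, mustWork = FALSE),
                 normalizePath(registry$user_dir, mustWork = FALSE))) {
    unlink(f)
  }
  invisible(registry)
}

#' List registry contents
#' @param registry a [model_registry()].
#' @return data.frame with columns \code{name}, \code{kind},
#'   \code{output_kind} (NA for cells), \code{protected}, \code{delayed}.
#' @export
list_models <- function(registry) {
  tt <- registry$types
  data.frame(
    name = vapply(tt, `[[`, "", "name"),
    kind = vapply(tt, `[[`, "", "kind"),
    output_kind = vapply(tt, function(d) d$output_kind %||% NA_character_, ""),
    protected = vapply(tt, `[[`, FALSE, "protected"),
    delayed = vapply(tt, function(d) isTRUE(d$delayed), FALSE),
    row.names = NULL
  )
}

#' @export
print.model_registry <- function(x, ...) {
  df <- list_models(x)
  cat(sprintf("<model registry> %d cell types, %d synapse types\n",
              sum(df$kind == "cell"), sum(df$kind == "synapse")))
  print(df)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Compiled evaluation

#' Vectorized vector field of a compiled cell type
#'
#' Returns \code{function(state, params, inputs)} evaluating the definition's
#' aux functions (in declaration order) and then every rhs expression, over
#' vector-valued state (one element per cell of a layer).
#'
#' @param def a [cell_type_def()].
#' @return function returning a named list of derivative vectors.
#' @export
cell_rhs_fun <- function(def) {
  force(def)
  function(state, params, inputs) {
    env <- list2env(c(state, params, inputs), parent = .expr_env)
    for (an in names(def$aux_functions)) {
      assign(an, eval(def$aux_functions[[an]]$ast, envir = env), envir = env)
    }
    out <- lapply(def$rhs, function(e) eval(e$ast, envir = env))
    out
  }
}

#' Vectorized outputs of a compiled cell type
#' @param def a [cell_type_def()].
#' @return function(state, params) returning a named list of output vectors.
#' @export
cell_outputs_fun <- function(def) {
  force(def)
  function(state, params) {
    env <- list2env(c(state, params), parent = .expr_env)
    for (an in names(def$aux_functions)) {
      assign(an, eval(def$aux_functions[[an]]$ast, envir = env), envir = env)
    }
    lapply(def$outputs, function(e) eval(e$ast, envir = env))
  }
}

#' Vectorized edge rule of a compiled synapse type
#'
#' Returns \code{function(pre_out, post_out, w_edge, params)} where
#' \code{pre_out}/\code{post_out} are named lists of the pre/post cells'
#' output values gathered per edge, and \code{w_edge} the geometric weights;
#' the result is the per-edge synaptic contribution.
#'
#' @param def a [synapse_type_def()].
#' @return function returning a numeric vector, one value per edge.
#' @export
synapse_rule_fun <- function(def) {
  force(def)
  function(pre_out, post_out, w_edge, params) {
    vals <- c(params, list(w_edge = w_edge))
    for (nm in def$pre_refs) vals[[paste0(nm, "_pre")]] <- pre_out[[nm]]
    for (nm in def$post_refs) vals[[paste0(nm, "_post")]] <- post_out[[nm]]
    eval(def$rule$ast, envir = vals, enclos = .expr_env)
  }
}
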