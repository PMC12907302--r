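#' @importFrom stats setNames
NULL

# Function set available inside model equations. min/max are elementwise
# (pmin/pmax) because cell equations are evaluated over whole layers at once.
# Division and log are guarded: a zero divisor or non-positive log argument
# raises immediately instead of seeding NaN into a long simulation.
.expr_function_names <- c(
  "exp", "log", "erf", "tanh", "sqrt", "min", "max", "pow", "heaviside",
  "ifelse", "cos", "sin", "cosh", "sinh", "abs"
)

.expr_ops <- c("+", "-", "*", "/", "^", "(", ">", "<", ">=", "<=", "==")

#' Error function
#'
#' Gauss error function, \code{erf(x) = 2/sqrt(pi) * integral_0^x exp(-t^2) dt},
#' used by sigmoidal rate transfer functions such as
#' \code{f(x) = (1 + erf(g x / sqrt(2))) / 2}.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' erf(0)      # 0
#' erf(Inf)    # 1
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Heaviside step function
#'
#' Right-continuous-at-zero convention is \emph{not} used here:
#' \code{heaviside(0) == 0}, matching the strict inequality of the
#' piecewise-linear rectifier used by the cell models.
#'
#' @param x numeric vector.
#' @return numeric vector of 0/1.
#' @export
heaviside <- function(x) as.numeric(x > 0)

.guarded_div <- function(a, b) {
  if (any(b == 0, na.rm = TRUE)) {
    stop(expr_error("division by zero during expression evaluation",
                    class = "retinet_eval_error"))
  }
  a / b
}

.guarded_log <- function(x) {
  if (any(x <= 0, na.rm = TRUE)) {
    stop(expr_error("log of a non-positive value during expression evaluation",
                    class = "retinet_eval_error"))
  }
  log(x)
}

# Shared evaluation environment for all compiled expressions.
.expr_env <- local({
  e <- new.env(parent = baseenv())
  e$erf <- erf
  e$heaviside <- heaviside
  e$pow <- function(a, b) a^b
  e$min <- function(...) Reduce(pmin, list(...))
  e$max <- function(...) Reduce(pmax, list(...))
  e$ifelse <- function(test, yes, no) ifelse(test, yes, no)
  e$`/` <- function(a, b) .guarded_div(a, b)
  e$log <- function(x) .guarded_log(x)
  e$pi <- pi
  e
})

expr_error <- function(msg, class, ...) {
  structure(
    class = c(class, "retinet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
}

#' Normalize a small LaTeX subset to the plain-ASCII equation dialect
#'
#' The canonical input dialect is plain ASCII infix (\code{"-(V - E_L)/tau"}).
#' A small LaTeX subset is tolerated and rewritten before parsing:
#' \code{\\frac\{a\}\{b\}}, function macros (\code{\\exp}, \code{\\tanh},
#' \code{\\sqrt}, \code{\\erf}, ...), \code{\\cdot}, \code{\\left}/\code{\\right},
#' and Greek-letter macros (\code{\\tau} becomes the symbol \code{tau}).
#'
#' @param src character scalar, equation text.
#' @return character scalar in the ASCII dialect.
#' @export
#' @examples
#' normalize_equation_text("\\frac{-(V - E_L)}{\\tau}")
normalize_equation_text <- function(src) {
  stopifnot(is.character(src), length(src) == 1L)
  s <- src
  # \frac{a}{b} -> ((a)/(b)); innermost-first so nested fractions resolve
  frac_rx <- "\\\\frac\\{([^{}]*)\\}\\{([^{}]*)\\}"
  while (grepl(frac_rx, s)) s <- gsub(frac_rx, "((\\1)/(\\2))", s)
  s <- gsub("\\\\left|\\\\right", "", s)
  s <- gsub("\\\\cdot|\\\\times", "*", s)
  greek <- c("alpha", "beta", "gamma", "delta", "epsilon", "theta", "kappa",
             "lambda", "mu", "nu", "sigma", "tau", "phi", "omega")
  for (g in greek) s <- gsub(paste0("\\\\", g, "\\b"), g, s)
  for (f in .expr_function_names) s <- gsub(paste0("\\\\", f, "\\b"), f, s)
  # remaining grouping braces act as parentheses
  s <- gsub("\\{", "(", s)
  s <- gsub("\\}", ")", s)
  s
}

validate_expr_ast <- function(ast, symbols, src) {
  walk <- function(node) {
    if (is.numeric(node) || is.logical(node)) return(invisible(NULL))
    if (is.name(node)) {
      nm <- as.character(node)
      if (nm == "pi") return(invisible(NULL))
      if (!nm %in% names(symbols)) {
        stop(expr_error(
          sprintf("undeclared symbol '%s' in \"%s\"", nm, src),
          class = "retinet_symbol_error", symbol = nm))
      }
      return(invisible(NULL))
    }
    if (is.call(node)) {
      head <- node[[1L]]
      if (!is.name(head)) {
        stop(expr_error(sprintf("unsupported construct in \"%s\"", src),
                        class = "retinet_parse_error"))
      }
      op <- as.character(head)
      if (op %in% .expr_ops) {
        for (i in seq_along(node)[-1L]) walk(node[[i]])
      } else if (op %in% .expr_function_names) {
        if (length(node) < 2L) {
          stop(expr_error(sprintf("function '%s' needs arguments in \"%s\"",
                                  op, src),
                          class = "retinet_function_error", fn = op))
        }
        for (i in seq_along(node)[-1L]) walk(node[[i]])
      } else {
        stop(expr_error(
          sprintf("unknown function '%s' in \"%s\"", op, src),
          class = "retinet_function_error", fn = op))
      }
      return(invisible(NULL))
    }
    stop(expr_error(sprintf("unsupported construct in \"%s\"", src),
                    class = "retinet_parse_error"))
  }
  walk(ast)
  invisible(NULL)
}

#' Compile equation text into an evaluable expression
#'
#' Parses plain ASCII infix arithmetic (optionally a small LaTeX subset, see
#' [normalize_equation_text()]) over a declared symbol table into an
#' [Expression][compile_expression] object. Every symbol must be declared;
#' the callable function set is fixed (\code{exp, log, erf, tanh, sqrt, min,
#' max, pow, heaviside, ifelse, cos, sin, cosh, sinh, abs}). Parsing is
#' deterministic: the same source always yields a structurally identical AST.
#'
#' @param src character scalar, the equation text.
#' @param symbols named character vector mapping symbol name to its kind
#'   (e.g. \code{c(V = "state", tau = "param", V_syn = "input")}). Only the
#'   names are used for validation; kinds are kept as metadata.
#' @return an object of class \code{"sim_expression"} with fields \code{src}
#'   (normalized source), \code{ast} (R language object) and \code{symbols}.
#' @export
#' @examples
#' e <- compile_expression("-(V - E_L)/tau",
#'                         c(V = "state", E_L = "param", tau = "param"))
#' eval_expression(e, list(V = -50, E_L = -60, tau = 0.1))  # -100
compile_expression <- function(src, symbols) {
  stopifnot(is.character(src), length(src) == 1L)
  if (is.null(names(symbols))) {
    # allow a plain character vector of names
    symbols <- setNames(rep("symbol", length(symbols)), symbols)
  }
  norm <- normalize_equation_text(src)
  ast <- tryCatch(
    str2lang(norm),
    error = function(e) {
      stop(expr_error(
        sprintf("parse error in \"%s\": %s", src, conditionMessage(e)),
        class = "retinet_parse_error"))
    }
  )
  if (!(is.call(ast) || is.name(ast) || is.numeric(ast))) {
    stop(expr_error(sprintf("parse error in \"%s\": not an expression", src),
                    class = "retinet_parse_error"))
  }
  validate_expr_ast(ast, symbols, src)
  structure(
    list(src = norm, ast = ast, symbols = symbols),
    class = "sim_expression"
  )
}

#' Evaluate a compiled expression at a symbol assignment
#'
#' Evaluation is pure and vectorized: supplying vectors for the state symbols
#' evaluates the expression elementwise (this is how whole layers are
#' advanced at once). Division by zero and log of a non-positive argument
#' raise an error of class \code{"retinet_eval_error"}.
#'
#' @param expr a \code{"sim_expression"} from [compile_expression()].
#' @param values named list (or environment) of symbol values.
#' @return numeric vector.
#' @export
eval_expression <- function(expr, values) {
  stopifnot(inherits(expr, "sim_expression"))
  eval(expr$ast, envir = values, enclos = .expr_env)
}

#' @export
print.sim_expression <- function(x, ...) {
  cat("<expression> ", x$src, "\n", sep = "")
  cat("  symbols: ", paste(names(x$symbols), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Names of symbols referenced by a compiled expression.
expr_symbols_used <- function(expr) {
  out <- character(0)
  walk <- function(node) {
    if (is.name(node)) {
      nm <- as.character(node)
      if (nm != "pi" && !nm %in% .expr_function_names && !nm %in% .expr_ops)
        out[[length(out) + 1L]] <<- nm
    } else if (is.call(node)) {
      for (i in seq_along(node)[-1L]) walk(node[[i]])
    }
  }
  walk(expr$ast)
  unique(out)
}
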