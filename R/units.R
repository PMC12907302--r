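# Default unit system and exact conversion factors. All computation happens
# in default units (time s, voltage mV, current pA, conductance nS, distance
# mm, capacitance nF, frequency Hz, molarity nM); conversion happens at model
# load and at output only. Units are metadata: no cross-quantity coherence
# checking is performed. The per-area alternatives (uA/cm^2, mS/cm^2,
# uF/cm^2) have no per-cell equivalent without a membrane area and are
# rejected.

.unit_table <- list(
  time        = c(s = 1, ms = 1e-3),
  voltage     = c(mV = 1, V = 1e3),
  current     = c(pA = 1, nA = 1e3),
  conductance = c(nS = 1, pS = 1e-3),
  distance    = c(mm = 1, um = 1e-3),
  capacitance = c(nF = 1, pF = 1e-3),
  frequency   = c(Hz = 1, kHz = 1e3),
  molarity    = c(nM = 1, uM = 1e3, mM = 1e6)
)

unit_error <- function(msg) {
  structure(
    class = c("retinet_unit_error", "retinet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

.unit_quantity <- function(unit) {
  for (q in names(.unit_table)) {
    if (unit %in% names(.unit_table[[q]])) return(q)
  }
  stop(unit_error(sprintf("unknown or unsupported unit '%s'", unit)))
}

#' Convert between listed units of the same physical quantity
#'
#' Exact factor conversion between a default unit and its listed
#' alternatives (\code{s/ms}, \code{mV/V}, \code{pA/nA}, \code{nS/pS},
#' \code{mm/um}, \code{nF/pF}, \code{Hz/kHz}, \code{nM/uM/mM}). Converting
#' across quantities (or to a per-area unit) raises a
#' \code{retinet_unit_error}.
#'
#' @param value numeric.
#' @param from,to unit names.
#' @return converted numeric value.
#' @export
#' @examples
#' convert_units(1000, "ms", "s")  # 1
#' convert_units(1, "V", "mV")     # 1000
convert_units <- function(value, from, to) {
  qf <- .unit_quantity(from)
  qt <- .unit_quantity(to)
  if (!identical(qf, qt)) {
    stop(unit_error(sprintf(
      "cannot convert '%s' (%s) to '%s' (%s): different physical quantities",
      from, qf, to, qt)))
  }
  tab <- .unit_table[[qf]]
  value * tab[[from]] / tab[[to]]
}

#' Default unit of a physical quantity
#' @param quantity one of \code{names(retinet_units())}.
#' @return unit name.
#' @export
default_unit <- function(quantity) {
  tab <- .unit_table[[quantity]]
  if (is.null(tab)) stop(unit_error(sprintf("unknown quantity '%s'", quantity)))
  names(tab)[tab == 1][1]
}

#' The supported unit table
#' @return named list: quantity -> named vector of factors relative to the
#'   default unit.
#' @export
retinet_units <- function() .unit_table
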