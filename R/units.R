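#' Unit conversion helpers
#'
#' The package works in SI units internally (m, s, kg, Pa.s, N/m, rad/s).
#' The microfluidics literature mixes centipoise, mN/m, micrometres, rpm
#' and Hz freely; these helpers perform the conversion explicitly at the
#' boundary so no magic factors appear inside the solver.
#'
#' @param x numeric value(s) in the source unit.
#' @return numeric value(s) in the SI unit.
#' @name units
NULL

#' @rdname units
#' @export
from_cP <- function(x) x * 1e-3          # centipoise -> Pa.s

#' @rdname units
#' @export
from_mN_per_m <- function(x) x * 1e-3    # mN/m -> N/m

#' @rdname units
#' @export
from_um <- function(x) x * 1e-6          # micrometre -> m

#' @rdname units
#' @export
from_mm <- function(x) x * 1e-3          # millimetre -> m

#' @rdname units
#' @export
from_rpm <- function(x) x * 2 * pi / 60  # revolutions/min -> rad/s

#' @rdname units
#' @export
from_hz <- function(x) x * 2 * pi        # revolutions/s -> rad/s

# internal: stop with the offending field name, used by all constructors
check_positive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop(sprintf("field '%s' must be a single positive finite number (got %s)",
                 field, paste(format(value), collapse = ", ")), call. = FALSE)
  invisible(value)
}

check_nonnegative <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0)
    stop(sprintf("field '%s' must be a single non-negative finite number (got %s)",
                 field, paste(format(value), collapse = ", ")), call. = FALSE)
  invisible(value)
}
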