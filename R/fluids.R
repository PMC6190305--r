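#' Fluid properties
#'
#' A single Newtonian phase: density and dynamic viscosity.
#'
#' @param density mass density in kg/m^3 (must be > 0).
#' @param viscosity dynamic viscosity in Pa.s (must be > 0). Use
#'   [from_cP()] to convert centipoise values.
#' @param name optional label used in printing.
#' @return an object of class `fluid_properties`.
#' @examples
#' silicone_oil <- fluid_properties(908.7, from_cP(64.3), "silicone oil")
#' water <- fluid_properties(997, from_cP(1.003), "water")
#' @export
fluid_properties <- function(density, viscosity, name = "fluid") {
  check_positive(density, "density")
  check_positive(viscosity, "viscosity")
  structure(list(density = density, viscosity = viscosity, name = name),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid> %s: rho = %g kg/m^3, eta = %g Pa.s\n",
              x$name, x$density, x$viscosity))
  invisible(x)
}

#' Immiscible fluid pair
#'
#' Continuous and dispersed phase plus the interfacial properties that
#' govern emulsification: interfacial tension and the static wall contact
#' angles. The contact angle of the dispersed phase is measured through
#' the dispersed phase at the wall; the continuous-phase angle (if known)
#' is stored for reference.
#'
#' @param continuous,dispersed [fluid_properties()] objects.
#' @param sigma interfacial tension in N/m (> 0). Use [from_mN_per_m()].
#' @param theta_dispersed static contact angle of the dispersed phase in
#'   degrees, in (0, 180).
#' @param theta_continuous optional continuous-phase contact angle in
#'   degrees.
#' @return an object of class `fluid_pair`.
#' @export
fluid_pair <- function(continuous, dispersed, sigma,
                       theta_dispersed = 90, theta_continuous = NULL) {
  stopifnot(inherits(continuous, "fluid_properties"),
            inherits(dispersed, "fluid_properties"))
  check_positive(sigma, "sigma")
  if (theta_dispersed <= 0 || theta_dispersed >= 180)
    stop("field 'theta_dispersed' must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  structure(list(continuous = continuous, dispersed = dispersed,
                 sigma = sigma, theta_dispersed = theta_dispersed,
                 theta_continuous = theta_continuous),
            class = "fluid_pair")
}

#' Density difference of a fluid pair
#'
#' @param pair a [fluid_pair()].
#' @param signed if `FALSE` (default) return the absolute difference,
#'   otherwise dispersed minus continuous.
#' @return density difference in kg/m^3.
#' @export
delta_rho <- function(pair, signed = FALSE) {
  d <- pair$dispersed$density - pair$continuous$density
  if (signed) d else abs(d)
}

#' @export
print.fluid_pair <- function(x, ...) {
  cat("<fluid_pair>\n")
  cat(sprintf("  continuous: %s (rho %g, eta %g)\n",
              x$continuous$name, x$continuous$density, x$continuous$viscosity))
  cat(sprintf("  dispersed : %s (rho %g, eta %g)\n",
              x$dispersed$name, x$dispersed$density, x$dispersed$viscosity))
  cat(sprintf("  sigma = %g N/m, theta_dispersed = %g deg\n",
              x$sigma, x$theta_dispersed))
  invisible(x)
}

#' Built-in fluid pairs
#'
#' The two working fluid pairs of the study: `device` is silicone oil
#' (continuous) with water (dispersed) on PDMS walls; `validation` is
#' sunflower oil with water on cyclo-olefin copolymer, matching the
#' rotating flow-focusing benchmark.
#'
#' @param which "device" or "validation".
#' @return a [fluid_pair()].
#' @export
builtin_fluid_pair <- function(which = c("device", "validation")) {
  which <- match.arg(which)
  if (which == "device") {
    fluid_pair(
      continuous = fluid_properties(908.7, from_cP(64.3), "silicone oil"),
      dispersed  = fluid_properties(997,   from_cP(1.003), "water"),
      sigma = from_mN_per_m(14.26),
      theta_dispersed = 112,      # water on native PDMS
      theta_continuous = 26.44)   # silicone oil on PDMS
  } else {
    fluid_pair(
      continuous = fluid_properties(909,  from_cP(62.2), "sunflower oil"),
      dispersed  = fluid_properties(1005, from_cP(1.09), "water"),
      sigma = from_mN_per_m(28.33),
      theta_dispersed = 82.7,     # water on cyclo-olefin copolymer
      theta_continuous = 10.3)
  }
}
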