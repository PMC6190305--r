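#' Dimensionless groups for centrifugal droplet microfluidics
#'
#' The design rules of a lab-on-a-disc emulsifier: the capillary number
#' of the continuous phase and Weber number of the dispersed phase
#' (dripping/jetting), the Bond number (centrifugal vs interfacial
#' effects, droplet formation), the centrifugal pumping velocity, and the
#' Rossby number (Coriolis vs centrifugal effects, outlet selection at
#' the separation junction).
#'
#' @name dimensionless
NULL

#' @describeIn dimensionless Capillary number Ca = eta_CP V_CP / sigma.
#' @param eta_cp continuous-phase dynamic viscosity (Pa.s).
#' @param v_cp continuous-phase velocity (m/s).
#' @param sigma interfacial tension (N/m), > 0.
#' @export
capillary_number <- function(eta_cp, v_cp, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  eta_cp * v_cp / sigma
}

#' @describeIn dimensionless Weber number We = rho_DP L V_DP^2 / sigma.
#' @param rho_dp dispersed-phase density (kg/m^3).
#' @param L characteristic length (m), > 0 (hydraulic diameter of the
#'   channel, or the nozzle dimension).
#' @param v_dp dispersed-phase velocity (m/s).
#' @export
weber_number <- function(rho_dp, L, v_dp, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(L <= 0)) stop("L must be > 0", call. = FALSE)
  rho_dp * L * v_dp^2 / sigma
}

#' @describeIn dimensionless Bond number Bo = |drho| r Omega^2 L^2 / sigma,
#'   the ratio of centrifugal to interfacial effects on the droplet.
#' @param drho density difference between dispersed and continuous phase
#'   (kg/m^3); the absolute value is used.
#' @param r radius from the rotation center (m), >= 0.
#' @param omega rotation speed (rad/s).
#' @export
bond_number <- function(drho, r, omega, L, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  if (any(r < 0) || any(L < 0)) stop("r and L must be >= 0", call. = FALSE)
  abs(drho) * r * omega^2 * L^2 / sigma
}

#' @describeIn dimensionless Mean velocity of centrifugally pumped liquid,
#'   U = Dh^2 rho Omega^2 rbar dr / (32 eta c).
#' @param Dh hydraulic diameter (m).
#' @param rho liquid density (kg/m^3).
#' @param rbar mean radial position of the liquid column (m).
#' @param dr radial extent of the liquid column (m).
#' @param eta liquid dynamic viscosity (Pa.s), > 0.
#' @param c length of the liquid column along the channel (m), > 0.
#' @export
mean_channel_velocity <- function(Dh, rho, omega, rbar, dr, eta, c) {
  if (any(c <= 0)) stop("c must be > 0", call. = FALSE)
  if (any(eta <= 0)) stop("eta must be > 0", call. = FALSE)
  Dh^2 * rho * omega^2 * rbar * dr / (32 * eta * c)
}

#' @describeIn dimensionless Rossby number Ro = rho Omega Dh^2 / eta, the
#'   ratio of Coriolis to centrifugal effects for a centrifugally pumped
#'   phase (independent of radius; assumes the liquid column's radial
#'   extent equals its channel length). Evaluate it per phase with that
#'   phase's density and viscosity: the phase contrast in Ro is what
#'   separates droplets from the continuous stream at the bifurcation.
#' @param eta dynamic viscosity of the evaluated phase (Pa.s), > 0.
#' @export
rossby_number <- function(rho, omega, Dh, eta) {
  if (any(eta <= 0)) stop("eta must be > 0", call. = FALSE)
  rho * abs(omega) * Dh^2 / eta
}

#' @describeIn dimensionless Dripping/jetting regime: dripping iff both
#'   Ca_CP < ca_star and We_DP < we_star (strict; on-threshold values
#'   classify as jetting). Defaults are the literature-standard
#'   dripping-to-jetting scales.
#' @param ca_cp,we_dp capillary and Weber numbers.
#' @param ca_star,we_star regime thresholds, > 0.
#' @export
classify_dripping_jetting <- function(ca_cp, we_dp, ca_star = 0.1, we_star = 1.0) {
  if (ca_star <= 0 || we_star <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  ifelse(ca_cp < ca_star & we_dp < we_star, "dripping", "jetting")
}

#' @describeIn dimensionless Outlet selection at the separation junction:
#'   outlet A (radially outward) iff Ro < 1, else outlet B (lateral).
#' @param ro Rossby number, >= 0.
#' @export
classify_outlet <- function(ro) {
  if (any(ro < 0)) stop("Ro must be >= 0", call. = FALSE)
  ifelse(ro < 1, "A", "B")
}

#' Dimensionless characterization of a case
#'
#' Evaluates all dimensionless groups for a case at a given rotation
#' speed: Ca_CP, We_DP, Bo, per-phase Ro, the centrifugal pumping
#' velocity (if the case specifies pumping parameters), and the implied
#' regime and outlet classifications.
#'
#' @param case a `vof_case` from [build_case()].
#' @param omega rotation speed in rad/s; defaults to the case's final
#'   speed.
#' @param r evaluation radius (m); defaults to the case's T-junction
#'   radial station.
#' @param L_convention characteristic length for Bo and We: "hydraulic"
#'   (the channel hydraulic diameter, default) or "nozzle" (the
#'   dispersed-phase nozzle width).
#' @return object of class `dimensionless_set`.
#' @export
dimensionless_set <- function(case, omega = NULL, r = NULL,
                              L_convention = c("hydraulic", "nozzle")) {
  stopifnot(inherits(case, "vof_case"))
  L_convention <- match.arg(L_convention)
  if (is.null(omega)) omega <- case$rotation$omega_final
  if (is.null(r)) r <- case$meta$r_eval %||% 32e-3
  ch <- case$layout$channel
  L <- if (L_convention == "hydraulic") ch$Dh else
    (case$layout$meta$W_constriction %||% ch$Dh)
  fl <- case$fluids
  v_cp <- inlet_velocity(case, "cp", omega)
  v_dp <- inlet_velocity(case, "dp", omega)
  ca <- capillary_number(fl$continuous$viscosity, v_cp, fl$sigma)
  we <- weber_number(fl$dispersed$density, L, v_dp, fl$sigma)
  bo <- bond_number(delta_rho(fl), r, omega, L, fl$sigma)
  ro_cp <- rossby_number(fl$continuous$density, omega, ch$Dh,
                         fl$continuous$viscosity)
  ro_dp <- rossby_number(fl$dispersed$density, omega, ch$Dh,
                         fl$dispersed$viscosity)
  structure(list(
    omega = omega, r = r, L = L, L_convention = L_convention,
    U_cp = v_cp, U_dp = v_dp,
    Ca_CP = ca, We_DP = we, Bo = bo,
    Ro_continuous = ro_cp, Ro_dispersed = ro_dp,
    regime = classify_dripping_jetting(ca, we),
    outlet_continuous = classify_outlet(ro_cp),
    outlet_dispersed = classify_outlet(ro_dp)),
    class = "dimensionless_set")
}

#' @export
print.dimensionless_set <- function(x, ...) {
  cat(sprintf("<dimensionless_set> Omega = %g rad/s, r = %g mm, L = %.4g um (%s)\n",
              x$omega, x$r * 1e3, x$L * 1e6, x$L_convention))
  cat(sprintf("  Ca_CP = %.4g  We_DP = %.4g  ->  %s\n", x$Ca_CP, x$We_DP, x$regime))
  cat(sprintf("  Bo = %.4g\n", x$Bo))
  cat(sprintf("  Ro(continuous) = %.4g -> outlet %s;  Ro(dispersed) = %.4g -> outlet %s\n",
              x$Ro_continuous, x$outlet_continuous,
              x$Ro_dispersed, x$outlet_dispersed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean inlet velocity of a phase at rotation speed omega; fixed inlet
# velocities of rotating cases are taken as calibrated at omega_final and
# scaled with omega^2 (centrifugal pumping scaling)
inlet_velocity <- function(case, phase = c("cp", "dp"), omega = NULL,
                           fluid = NULL) {
  phase <- match.arg(phase)
  sp <- case$inlets[[phase]]
  if (is.null(sp)) return(0)
  if (is.null(omega)) omega <- case$rotation$omega_final
  if (sp$mode == "fixed") {
    of <- case$rotation$omega_final
    scale <- if (of > 0) (omega / of)^2 else 1
    return(sp$velocity * scale)
  }
  if (is.null(fluid))
    fluid <- if (phase == "cp") case$fluids$continuous else case$fluids$dispersed
  mean_channel_velocity(case$layout$channel$Dh, fluid$density, omega,
                        sp$rbar, sp$dr, fluid$viscosity, sp$c)
}

#' Dimensionless sweep over rotation speeds
#'
#' @param case a `vof_case`.
#' @param omegas vector of rotation speeds (rad/s).
#' @param ... passed to [dimensionless_set()].
#' @return data.frame with one row per speed: Ca, We, Bo, per-phase Ro
#'   and velocities, regime and outlet classifications.
#' @export
sweep_numbers <- function(case, omegas, ...) {
  rows <- lapply(omegas, function(om) {
    d <- dimensionless_set(case, omega = om, ...)
    data.frame(omega = om, U_cp = d$U_cp, U_dp = d$U_dp,
               Ca_CP = d$Ca_CP, We_DP = d$We_DP, Bo = d$Bo,
               Ro_continuous = d$Ro_continuous, Ro_dispersed = d$Ro_dispersed,
               regime = d$regime,
               outlet_continuous = d$outlet_continuous,
               outlet_dispersed = d$outlet_dispersed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
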