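#' Rotation schedule
#'
#' The disc is stationary initially and spins up along a linear ramp to
#' its final speed. `t_ramp = 0` requests a step start; the angular
#' acceleration is then reported as 0 with a warning (the Euler term of a
#' true step is a delta function and is not representable).
#'
#' @param omega_final final rotation speed in rad/s (>= 0). Use
#'   [from_hz()] / [from_rpm()] to convert.
#' @param t_ramp ramp duration in s (>= 0); default 10 ms.
#' @param sense +1 counterclockwise, -1 clockwise.
#' @return object of class `rotation_schedule`.
#' @export
rotation_schedule <- function(omega_final, t_ramp = 0.01, sense = 1) {
  check_nonnegative(omega_final, "omega_final")
  check_nonnegative(t_ramp, "t_ramp")
  if (!sense %in% c(-1, 1)) stop("field 'sense' must be +1 or -1", call. = FALSE)
  structure(list(omega_final = omega_final, t_ramp = t_ramp, sense = sense),
            class = "rotation_schedule")
}

#' Numerical settings for the VOF solver
#'
#' @param dx cell size in m (default 20 um, the accepted mesh of the
#'   mesh-sensitivity study).
#' @param cfl advective CFL limit in (0, 1].
#' @param capillary_safety safety factor on the capillary time-step bound
#'   sqrt((rho_CP + rho_DP) dx^3 / (4 pi sigma)).
#' @param p_tol pressure-solver tolerance (relative residual).
#' @param max_outer maximum outer iterations / corrector sweeps.
#' @param residual_tol convergence threshold on scaled residuals (the
#'   reference runs used 1e-6; coarser desk-scale defaults are accepted).
#' @param alpha_clip volume-fraction clipping tolerance.
#' @param dt_max hard cap on the time step in s.
#' @param strict_dt if TRUE, use a fixed 1e-7 s time step (the reference
#'   configuration) instead of the adaptive bound.
#' @param hs_friction include the out-of-plane Hele-Shaw friction term
#'   -12 eta V / H^2 in planar-2D momentum (on for real channel cases,
#'   off for analytic toys).
#' @param n_corrector number of PISO pressure-correction sweeps (>= 2).
#' @param smooth_passes smoothing passes on alpha for normals/curvature.
#' @return object of class `numerics_config`.
#' @export
numerics_config <- function(dx = 20e-6, cfl = 0.4, capillary_safety = 0.9,
                            p_tol = 1e-9, max_outer = 50,
                            residual_tol = 1e-6, alpha_clip = 1e-8,
                            dt_max = 2e-5, strict_dt = FALSE,
                            hs_friction = TRUE, n_corrector = 2,
                            smooth_passes = 2) {
  check_positive(dx, "dx")
  if (cfl <= 0 || cfl > 1) stop("field 'cfl' must be in (0, 1]", call. = FALSE)
  check_positive(p_tol, "p_tol")
  check_positive(residual_tol, "residual_tol")
  check_positive(alpha_clip, "alpha_clip")
  if (n_corrector < 2) stop("field 'n_corrector' must be >= 2", call. = FALSE)
  structure(list(dx = dx, cfl = cfl, capillary_safety = capillary_safety,
                 p_tol = p_tol, max_outer = max_outer,
                 residual_tol = residual_tol, alpha_clip = alpha_clip,
                 dt_max = dt_max, strict_dt = strict_dt,
                 hs_friction = hs_friction, n_corrector = n_corrector,
                 smooth_passes = smooth_passes),
            class = "numerics_config")
}

#' Inlet velocity specification
#'
#' Either an explicit mean velocity, or "derive from centrifugal
#' pumping": U = Dh^2 rho Omega^2 rbar dr / (32 eta c) evaluated at run
#' time with the instantaneous rotation speed.
#'
#' @param velocity explicit mean inlet velocity in m/s, or NULL.
#' @param rbar,dr,c centrifugal pumping parameters in m (mean radial
#'   position of the liquid column, its radial extent, and its length
#'   along the channel); used when `velocity` is NULL.
#' @return a list tagged with its mode.
#' @export
inlet_spec <- function(velocity = NULL, rbar = NULL, dr = NULL, c = NULL) {
  if (!is.null(velocity)) {
    check_nonnegative(velocity, "velocity")
    return(list(mode = "fixed", velocity = velocity))
  }
  if (is.null(rbar) || is.null(dr) || is.null(c))
    stop("inlet_spec: give either 'velocity' or all of 'rbar', 'dr', 'c'",
         call. = FALSE)
  check_positive(c, "c")
  list(mode = "pumping", rbar = rbar, dr = dr, c = c)
}

case_ids <- c("device", "validation_24Hz", "validation_40Hz",
              "static_droplet", "patch_advection", "rotating_channel")

#' Build a complete simulation case
#'
#' Constructs a fully populated case definition for one of the built-in
#' configurations, with printed reference values as defaults:
#'
#' * `device`: the lab-on-a-disc emulsification/separation device
#'   (silicone oil / water, 200 x 100 um channels, 108 mm disc).
#' * `validation_24Hz`, `validation_40Hz`: the rotating flow-focusing
#'   benchmark (sunflower oil / water, 660/376 um wide, 200 um deep,
#'   25 mm droplet channel, 80 deg junction) at 24 or 40 Hz.
#' * `static_droplet`: quiescent closed box with a centered circular
#'   dispersed patch of radius 50 um, no rotation.
#' * `patch_advection`: straight channel used for interface-advection
#'   verification.
#' * `rotating_channel`: single-phase radial channel for the
#'   Coriolis/mesh-sensitivity verification.
#'
#' @param case_id one of the ids above.
#' @param overrides named list of overrides, nested as in the case
#'   structure (e.g. `list(numerics = list(dx = 1e-5))`). Unknown field
#'   names are an error naming the field.
#' @return object of class `vof_case` with fields `case_id`, `layout`,
#'   `fluids`, `rotation`, `numerics`, `inlets`, `run` (run window and
#'   snapshot cadence), `meta`.
#' @examples
#' case <- build_case("validation_24Hz")
#' case$fluids$continuous$viscosity   # 0.0622 Pa.s
#' @export
build_case <- function(case_id, overrides = list()) {
  if (!is.character(case_id) || length(case_id) != 1L || !case_id %in% case_ids)
    stop(sprintf("unknown case_id '%s'; known: %s",
                 paste(case_id, collapse = ","),
                 paste(case_ids, collapse = ", ")), call. = FALSE)
  case <- switch(case_id,
    device = list(
      case_id = case_id,
      layout = device_layout(),
      fluids = builtin_fluid_pair("device"),
      rotation = rotation_schedule(150),
      numerics = numerics_config(),
      # mean feed velocities at the final rotation speed; Ca_CP ~ 0.11,
      # inside the dripping window for this viscosity contrast
      inlets = list(cp = inlet_spec(velocity = 0.025),
                    dp = inlet_spec(velocity = 0.015)),
      run = list(t_end = 0.02, snapshot_dt = 5e-4),
      meta = list(r_eval = 32e-3)),
    validation_24Hz = validation_case(24),
    validation_40Hz = validation_case(40),
    static_droplet = list(
      case_id = case_id,
      layout = toy_layout("box", size = 200e-6),
      fluids = builtin_fluid_pair("device"),
      rotation = rotation_schedule(0, t_ramp = 0),
      numerics = numerics_config(dx = 2.5e-6, hs_friction = FALSE),
      inlets = list(),
      run = list(t_end = 5e-5, snapshot_dt = 5e-5),
      meta = list(droplet_radius = 50e-6, center = c(100e-6, 100e-6))),
    patch_advection = list(
      case_id = case_id,
      layout = toy_layout("channel", size = 2e-3, W = 400e-6),
      fluids = builtin_fluid_pair("device"),
      rotation = rotation_schedule(0, t_ramp = 0),
      numerics = numerics_config(hs_friction = FALSE),
      inlets = list(cp = inlet_spec(velocity = 0.05)),
      run = list(t_end = 1e-3, snapshot_dt = 1e-3),
      meta = list()),
    rotating_channel = list(
      case_id = case_id,
      layout = toy_layout("radial_expansion", size = 1e-3, W = 200e-6,
                          H = 100e-6, r_start = 30e-3),
      # working fluid is water: the high-Rossby phase is the one the
      # Coriolis force visibly deflects (the low-Ro silicone oil gives
      # an irrotational Coriolis contribution in the disc plane)
      fluids = fluid_pair(
        fluid_properties(997, from_cP(1.003), "water"),
        fluid_properties(908.7, from_cP(64.3), "silicone oil"),
        from_mN_per_m(14.26), 68),
      rotation = rotation_schedule(150, t_ramp = 2e-4),
      numerics = numerics_config(hs_friction = FALSE),
      inlets = list(cp = inlet_spec(velocity = 0.02)),
      run = list(t_end = 3e-3, snapshot_dt = 3e-4),
      meta = list())
  )
  case <- apply_overrides(case, overrides)
  class(case) <- "vof_case"
  validate_case(case)
  case
}

validation_case <- function(hz) {
  list(
    case_id = sprintf("validation_%dHz", hz),
    layout = validation_layout(),
    fluids = builtin_fluid_pair("validation"),
    rotation = rotation_schedule(from_hz(hz)),
    numerics = numerics_config(),
    # Ca_CP = 0.16 for the benchmark fixes the continuous-phase mean
    # velocity at 0.0729 m/s; the dispersed feed is not printed and is
    # set to give a moderate flow-rate ratio.
    inlets = list(cp = inlet_spec(velocity = 0.0729),
                  dp = inlet_spec(velocity = 0.05)),
    run = list(t_end = 0.05, snapshot_dt = 1e-3),
    meta = list(r_eval = 32e-3, bo_printed = if (hz == 24) 0.09 else 0.25))
}

# deep-merge overrides into a case, validating field names
apply_overrides <- function(base, overrides, path = "") {
  if (!length(overrides)) return(base)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop(sprintf("overrides%s must be a named list", path), call. = FALSE)
  for (nm in names(overrides)) {
    full <- paste0(path, "$", nm)
    if (!nm %in% names(base))
      stop(sprintf("override names unknown field '%s'", full), call. = FALSE)
    v <- overrides[[nm]]
    if (is.list(v) && is.list(base[[nm]]) && !inherits(v, "channel_layout") &&
        is.null(attr(v, "class"))) {
      base[[nm]] <- apply_overrides(base[[nm]], v, full)
    } else {
      base[[nm]] <- v
    }
  }
  base
}

validate_case <- function(case) {
  stopifnot(inherits(case$layout, "channel_layout"),
            inherits(case$fluids, "fluid_pair"),
            inherits(case$rotation, "rotation_schedule"),
            inherits(case$numerics, "numerics_config"))
  for (nm in names(case$inlets)) {
    sp <- case$inlets[[nm]]
    if (sp$mode == "fixed" && sp$velocity < 0)
      stop(sprintf("override with wrong sign: field 'inlets$%s$velocity' must be >= 0", nm),
           call. = FALSE)
  }
  invisible(case)
}

#' @export
print.vof_case <- function(x, ...) {
  cat(sprintf("<vof_case> %s\n", x$case_id))
  cat(sprintf("  layout : %s (W = %g um, H = %g um, Dh = %.4g um)\n",
              x$layout$name, x$layout$channel$width * 1e6,
              x$layout$channel$height * 1e6, x$layout$channel$Dh * 1e6))
  cat(sprintf("  fluids : %s / %s, sigma = %g mN/m\n",
              x$fluids$continuous$name, x$fluids$dispersed$name,
              x$fluids$sigma * 1e3))
  cat(sprintf("  rotation: Omega_final = %g rad/s (ramp %g ms)\n",
              x$rotation$omega_final, x$rotation$t_ramp * 1e3))
  cat(sprintf("  numerics: dx = %g um, CFL = %g\n",
              x$numerics$dx * 1e6, x$numerics$cfl))
  invisible(x)
}

# ---- serialization ---------------------------------------------------

# Cases serialize to structured YAML. Layouts are rebuilt from their
# segment/port tables, so the round trip is field-by-field faithful.
case_to_list <- function(case) {
  lay <- case$layout
  list(
    case_id = case$case_id,
    layout = list(name = lay$name, depth = lay$depth,
                  disc_radius = lay$disc_radius,
                  channel = unclass(lay$channel)[c("width", "height", "length")],
                  segments = lapply(seq_len(nrow(lay$segments)),
                                    function(k) as.list(lay$segments[k, ])),
                  prefill = if (is.null(lay$prefill)) NULL else
                    lapply(seq_len(nrow(lay$prefill)),
                           function(k) as.list(lay$prefill[k, ])),
                  ports = lapply(lay$ports, function(p)
                    list(name = p$name, kind = p$kind,
                         center = as.numeric(p$center),
                         normal = as.numeric(p$normal),
                         width = p$width, outlet_id = p$outlet_id)),
                  meta = lay$meta),
    fluids = list(
      continuous = unclass(case$fluids$continuous),
      dispersed = unclass(case$fluids$dispersed),
      sigma = case$fluids$sigma,
      theta_dispersed = case$fluids$theta_dispersed,
      theta_continuous = case$fluids$theta_continuous),
    rotation = unclass(case$rotation),
    numerics = unclass(case$numerics),
    inlets = case$inlets,
    run = case$run,
    meta = case$meta)
}

case_from_list <- function(x) {
  segs <- do.call(rbind, lapply(x$layout$segments, as.data.frame))
  ports <- lapply(x$layout$ports, function(p)
    make_port(p$name, p$kind, as.numeric(p$center), as.numeric(p$normal),
              p$width, if (is.null(p$outlet_id)) NA_character_ else p$outlet_id))
  ch <- x$layout$channel
  lay <- new_layout(segs, ports,
                    rect_channel(ch$width, ch$height, ch$length),
                    x$layout$depth,
                    disc_radius = if (is.null(x$layout$disc_radius))
                      NA_real_ else x$layout$disc_radius,
                    meta = x$layout$meta, name = x$layout$name,
                    prefill = if (is.null(x$layout$prefill)) NULL else
                      do.call(rbind, lapply(x$layout$prefill, as.data.frame)))
  fl <- x$fluids
  fluids <- fluid_pair(
    fluid_properties(fl$continuous$density, fl$continuous$viscosity,
                     fl$continuous$name),
    fluid_properties(fl$dispersed$density, fl$dispersed$viscosity,
                     fl$dispersed$name),
    fl$sigma, fl$theta_dispersed, fl$theta_continuous)
  case <- list(case_id = x$case_id, layout = lay, fluids = fluids,
               rotation = do.call(rotation_schedule, x$rotation),
               numerics = do.call(numerics_config, x$numerics),
               inlets = x$inlets, run = x$run, meta = x$meta)
  class(case) <- "vof_case"
  validate_case(case)
  case
}

#' Write / read a case file
#'
#' Cases serialize to a structured YAML text file and read back
#' field-by-field identical (to 15 significant digits).
#'
#' @param case a `vof_case`.
#' @param path file path.
#' @return `write_case` returns `path` invisibly; `read_case` returns the
#'   `vof_case`.
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "vof_case"))
  writeLines(yaml::as.yaml(case_to_list(case), precision = 15L), path)
  invisible(path)
}

#' @rdname write_case
#' @export
read_case <- function(path) {
  case_from_list(yaml::read_yaml(path))
}
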