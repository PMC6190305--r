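# Built-in solver verification suite: each check runs a small case with
# an analytic or independent reference and reports a pass/fail plus the
# measured value. These are the package's standing quality gates; the
# test suite and the `validate` CLI subcommand both run them.

#' Desk-scale single-junction device case
#'
#' A truncated variant of the device layout — one bifurcated junction,
#' one T-junction, one separation junction with outlets A and B — used
#' for desk-scale emulsification runs (trend studies over rotation
#' speed, outlet-selection checks). Geometry cross-sections, fluids and
#' wetting are those of the full device; only the channel lengths are
#' shortened and the grid is modestly coarsened so that droplet
#' generation is observable in minutes of compute.
#'
#' @param omega final rotation speed (rad/s).
#' @param t_end run window (s).
#' @param dx cell size (m); default 25 um (8 cells across the channel).
#' @param sub_length,sep_offset sub-channel geometry (m).
#' @param overrides further case overrides (applied last).
#' @return a `vof_case`.
#' @export
device_mini_case <- function(omega = 150, t_end = 0.05, dx = 25e-6,
                             sub_length = 2.4e-3, sep_offset = 1.6e-3,
                             overrides = list()) {
  lay <- device_layout(junction_radii = 24e-3, r_inlet = 23.2e-3,
                       sub_length = sub_length, t_offset = 0.6e-3,
                       dp_length = 0.6e-3, sep_offset = sep_offset,
                       outlet_length = 0.6e-3)
  ov <- list(layout = lay,
             rotation = rotation_schedule(omega, t_ramp = 2e-3),
             numerics = numerics_config(dx = dx),
             run = list(t_end = t_end, snapshot_dt = 1e-3),
             meta = list(r_eval = 24e-3))
  for (nm in names(overrides)) ov[[nm]] <- overrides[[nm]]
  build_case("device", ov)
}

#' Desk-scale rotating flow-focusing case
#'
#' A truncated variant of the flow-focusing benchmark (shortened droplet
#' channel, modestly coarsened grid) used for desk-scale emulsification
#' runs. Feed velocities scale with the square of the rotation speed
#' from the benchmark anchor (centrifugal pumping scaling), so a
#' rotation-frequency sweep changes shear and Bond number together, as
#' on the disc.
#'
#' @param hz rotation frequency in Hz (the benchmark anchors are 24 and
#'   40).
#' @param t_end run window (s).
#' @param dx cell size (m); default 30 um (22 cells across the droplet
#'   channel).
#' @param length truncated droplet-channel length (m).
#' @param overrides further case overrides (applied last).
#' @return a `vof_case`.
#' @export
validation_mini_case <- function(hz = 24, t_end = 0.06, dx = 30e-6,
                                 length = 2.5e-3, overrides = list()) {
  base <- build_case("validation_24Hz")
  scale <- (hz / 24)^2
  ov <- list(layout = validation_layout(length = length),
             rotation = rotation_schedule(from_hz(hz)),
             numerics = numerics_config(dx = dx),
             inlets = list(cp = inlet_spec(velocity = 0.0729 * scale),
                           dp = inlet_spec(velocity = 0.05 * scale)),
             run = list(t_end = t_end, snapshot_dt = 1e-3))
  for (nm in names(overrides)) ov[[nm]] <- overrides[[nm]]
  build_case("validation_24Hz", ov)
}

#' Emulsification trend over rotation speed
#'
#' Runs a desk-scale emulsification case at several rotation speeds and
#' summarizes the droplet population of each run: mean droplet area,
#' generation rate, and the Bond number of the operating point.
#'
#' @param cases list of `vof_case` objects (one per speed), or NULL to
#'   build flow-focusing mini cases at `hz`.
#' @param hz rotation frequencies in Hz (used when `cases` is NULL);
#'   defaults span the dripping window of the benchmark fluids.
#' @param min_cells satellite filter: pinch-off events smaller than
#'   this many cells are excluded from the population statistics.
#' @param drop_first discard the first (start-up transient) droplet of
#'   each run before averaging.
#' @param t_end run window(s) in s, recycled over the speeds (slower
#'   speeds need longer windows for the same droplet count).
#' @param ... passed to [validation_mini_case()].
#' @return data.frame with one row per speed: omega, Bo, n_droplets,
#'   mean_area (m^2), rate (1/s); the runs are attached as the
#'   `"runs"` attribute.
#' @export
emulsification_trend <- function(cases = NULL, hz = c(16, 20, 24),
                                 min_cells = 8, drop_first = TRUE,
                                 t_end = c(0.075, 0.05, 0.05), ...) {
  if (is.null(cases)) {
    t_end <- rep_len(t_end, length(hz))
    cases <- lapply(seq_along(hz), function(k)
      validation_mini_case(hz = hz[k], t_end = t_end[k], ...))
  }
  rows <- list(); runs <- list()
  for (k in seq_along(cases)) {
    case <- cases[[k]]
    run <- run_case(case)
    ev <- run$events[run$events$event == "pinch_off", , drop = FALSE]
    H <- case$layout$channel$height
    vmin <- min_cells * run$ctx$dx^2 * H
    ev <- ev[ev$volume >= vmin, , drop = FALSE]
    if (drop_first && nrow(ev)) ev <- ev[order(ev$time), ][-1, , drop = FALSE]
    window <- run$snapshots[[length(run$snapshots)]]$t
    d <- dimensionless_set(case)
    rows[[k]] <- data.frame(
      omega = case$rotation$omega_final,
      Bo = d$Bo,
      n_droplets = nrow(ev),
      mean_area = if (nrow(ev)) mean(ev$volume / H) else NA_real_,
      rate = nrow(ev) / window)
    runs[[k]] <- run
  }
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  out
}

check_result <- function(name, pass, value, target, detail = "") {
  data.frame(check = name, pass = pass, value = value, target = target,
             detail = detail, stringsAsFactors = FALSE)
}

#' Verification: static-droplet Laplace pressure
#'
#' A quiescent circular dispersed droplet of radius R in a closed box;
#' the measured pressure jump between droplet core and far field is
#' compared with the planar Young-Laplace value sigma/R.
#'
#' @param R droplet radius (m).
#' @param cells_per_radius grid resolution (default R/dx = 20).
#' @param n_steps relaxation steps before measuring.
#' @param tol relative tolerance on the pressure jump.
#' @return one-row data.frame (check, pass, value, target, detail).
#' @export
check_laplace <- function(R = 50e-6, cells_per_radius = 20, n_steps = 60,
                          tol = 0.05) {
  dx <- R / cells_per_radius
  case <- build_case("static_droplet",
                     list(numerics = list(dx = dx),
                          meta = list(droplet_radius = R,
                                      center = c(100e-6, 100e-6))))
  ctx <- init_solver(case)
  state <- init_state(ctx)
  for (k in seq_len(n_steps)) state <- step(state, ctx)$state
  dp <- laplace_jump(state, ctx, case$meta$center, R)
  target <- case$fluids$sigma / R
  spur <- max(abs(state$u), abs(state$v))
  check_result("laplace_pressure", abs(dp - target) / target < tol, dp, target,
               sprintf("rel.err %.3g, max spurious current %.3g m/s",
                       abs(dp - target) / target, spur))
}

# pressure jump: droplet core mean minus far-field mean
laplace_jump <- function(state, ctx, center, R) {
  g <- ctx$grid
  xc <- g$x0 + (seq_len(g$nx) - 0.5) * g$dx
  yc <- g$y0 + (seq_len(g$ny) - 0.5) * g$dx
  r2 <- outer((xc - center[1])^2, (yc - center[2])^2, "+")
  core <- r2 < (0.5 * R)^2 & g$mask
  far <- r2 > (1.4 * R)^2 & g$mask
  mean(state$p[core]) - mean(state$p[far])
}

#' Verification: square-patch advection
#'
#' A square dispersed patch translated by a uniform divergence-free
#' velocity over 10 cell widths: the dispersed volume must be conserved
#' to 1e-8 (relative) and the centroid displaced by 10 cells within a
#' tenth of a cell.
#'
#' @param n_cells translation distance in cells.
#' @param courant face Courant number per step.
#' @return one-row data.frame.
#' @export
check_patch_advection <- function(n_cells = 10, courant = 0.4) {
  case <- build_case("patch_advection")
  ctx <- init_solver(case)
  g <- ctx$grid
  alpha <- matrix(1, g$nx, g$ny)
  # 8x8-cell square patch inside the channel
  i0 <- 12L; j0 <- which(g$mask[i0, ])[3]
  alpha[i0:(i0 + 7), j0:(j0 + 7)] <- 0
  alpha[!g$mask] <- 1
  U <- 0.05
  u <- matrix(U, g$nx + 1, g$ny)
  v <- matrix(0, g$nx, g$ny + 1)
  dt <- courant * g$dx / U
  nstep <- ceiling(n_cells / courant)
  v0 <- sum(1 - alpha[g$mask])
  cx0 <- patch_centroid(alpha, g)
  for (s in seq_len(nstep))
    alpha <- advect_alpha(alpha, u, v, dt, ctx,
                          sweep_first = if (s %% 2) "x" else "y")$alpha
  v1 <- sum(1 - alpha[g$mask])
  cx1 <- patch_centroid(alpha, g)
  vol_err <- abs(v1 - v0) / v0
  disp_err <- abs((cx1 - cx0) / g$dx - nstep * courant)
  check_result("patch_advection",
               vol_err < 1e-8 && disp_err < 0.1,
               vol_err, 1e-8,
               sprintf("centroid displacement error %.3g cells", disp_err))
}

patch_centroid <- function(alpha, g) {
  w <- (1 - alpha) * g$mask
  xc <- g$x0 + (seq_len(g$nx) - 0.5) * g$dx
  sum(w * matrix(xc, g$nx, g$ny)) / sum(w)
}

#' Verification: rotating-channel throughflow deflection
#'
#' Single-phase flow in a radial channel opening into a wider chamber,
#' under rotation. In the planar disc plane a fully developed straight
#' profile cannot skew (the transverse Coriolis force is absorbed by
#' the pressure field), so the check measures the standard planar
#' manifestation: downstream of the expansion the throughflow jet
#' deflects toward the trailing wall, opposite the rotation sense. The
#' profile must be skewed to the trailing side under rotation and
#' symmetric without rotation.
#'
#' @param omega rotation speed (rad/s).
#' @param dx cell size (m).
#' @param t_end integration window (s).
#' @return one-row data.frame; the profile is attached as the
#'   `"profile"` attribute (data.frame y, u).
#' @export
check_rotating_profile <- function(omega = 150, dx = 20e-6, t_end = 3e-3) {
  run <- rotating_channel_run(omega, dx, t_end)
  pr <- chamber_profile(run)
  asym <- profile_asymmetry(pr)
  run0 <- rotating_channel_run(0, dx, t_end)
  pr0 <- chamber_profile(run0)
  asym0 <- profile_asymmetry(pr0)
  # trailing side for counterclockwise rotation (+z) and outward flow is -y
  res <- check_result("rotating_profile",
                      asym < -5 * max(1e-3, abs(asym0)),
                      asym, -1,
                      sprintf("skew %.4g (static %.4g); negative = trailing wall",
                              asym, asym0))
  attr(res, "profile") <- pr
  res
}

rotating_channel_run <- function(omega, dx, t_end) {
  # fixed 10 us step cap: the deflected jet is mildly time-sensitive,
  # so both resolutions are integrated with the same temporal accuracy
  case <- build_case("rotating_channel",
                     list(rotation = rotation_schedule(omega, t_ramp = 2e-4),
                          numerics = numerics_config(dx = dx,
                                                     dt_max = 1e-5,
                                                     hs_friction = FALSE)))
  run_case(case, t_end = t_end, snapshot_dt = t_end / 10,
           stop_when_steady = TRUE, steady_tol = 1e-5)
}

# throughflow (u) profile across the chamber, two thirds into it (the
# near-lip region carries the opposite-signed pressure adjustment of
# the expansion; the jet's Coriolis deflection dominates downstream)
chamber_profile <- function(run, frac = 2 / 3) {
  g <- run$ctx$grid
  st <- run$snapshots[[length(run$snapshots)]]
  meta <- run$case$layout$meta
  xs <- meta$chamber_start + frac * meta$chamber_length
  i <- round((xs - g$x0) / g$dx)
  rows <- which(g$mask[i, ])
  data.frame(y = g$y0 + (rows - 0.5) * g$dx,
             u = 0.5 * (st$u[i, rows] + st$u[i + 1, rows]))
}

# signed first moment of the profile about the channel centerline,
# normalized by the absolute flux; negative = peak shifted to -y
profile_asymmetry <- function(pr) {
  yc <- mean(range(pr$y))
  w <- (max(pr$y) - min(pr$y)) / 2
  sum(pr$u * (pr$y - yc)) / (sum(abs(pr$u)) * w)
}

# throughflow profile across the feed channel at its mid-length
midchannel_profile <- function(run, frac = 0.5) {
  g <- run$ctx$grid
  st <- run$snapshots[[length(run$snapshots)]]
  meta <- run$case$layout$meta
  xs <- meta$chamber_start - (1 - frac) * run$case$layout$channel$length
  i <- round((xs - g$x0) / g$dx)
  rows <- which(g$mask[i, ])
  data.frame(y = g$y0 + (rows - 0.5) * g$dx,
             u = 0.5 * (st$u[i, rows] + st$u[i + 1, rows]))
}

#' Verification: mesh sensitivity of the rotating-channel profile
#'
#' Repeats the rotating-channel flow at 20 um and 10 um resolution and
#' compares the mid-channel throughflow profiles (finer profile
#' interpolated to the coarse points): RMS difference below `tol` of the
#' profile maximum.
#'
#' @param omega rotation speed (rad/s).
#' @param tol relative RMS tolerance (default 5%).
#' @param t_end integration window (s).
#' @return one-row data.frame.
#' @export
check_mesh_pair <- function(omega = 150, tol = 0.05, t_end = 3e-3) {
  run1 <- rotating_channel_run(omega, 20e-6, t_end)
  pr1 <- midchannel_profile(run1)
  run2 <- rotating_channel_run(omega, 10e-6, t_end)
  pr2 <- midchannel_profile(run2)
  u2 <- stats::approx(pr2$y, pr2$u, xout = pr1$y, rule = 2)$y
  rms <- sqrt(mean((pr1$u - u2)^2)) / max(abs(pr1$u))
  check_result("mesh_pair", rms < tol, rms, tol,
               sprintf("profiles at dx = 20 and 10 um, %d/%d points",
                       nrow(pr1), nrow(pr2)))
}

#' Verification: stationary bifurcation splits the flow
#'
#' The single-junction device at zero rotation: pressure-driven flow
#' must leave through both outlet A and outlet B.
#'
#' @param t_end integration window (s).
#' @return one-row data.frame.
#' @export
check_bifurcation_split <- function(t_end = 1.5e-3) {
  case <- device_mini_case(omega = 0, t_end = t_end)
  case$rotation <- rotation_schedule(0, t_ramp = 0)
  run <- run_case(case, t_end = t_end, snapshot_dt = t_end)
  fl <- outlet_fluxes(run)
  check_result("bifurcation_split",
               all(fl > 0) && length(fl) == 2,
               min(fl) / max(fl), 0,
               sprintf("outlet fluxes A = %.3g, B = %.3g m^2/s",
                       fl[["A"]], fl[["B"]]))
}

#' Volumetric outflux per outlet of the final snapshot
#'
#' @param run a `vof_run`.
#' @return named vector (m^2/s in-plane flux) per outlet id.
#' @export
outlet_fluxes <- function(run) {
  ctx <- run$ctx
  st <- run$snapshots[[length(run$snapshots)]]
  faces <- ctx$grid$faces
  of <- faces[faces$tag == "outlet", , drop = FALSE]
  ids <- sort(unique(of$outlet_id))
  out <- stats::setNames(numeric(length(ids)), ids)
  for (k in seq_len(nrow(of))) {
    val <- if (of$axis[k] == "x") st$u[of$i[k], of$j[k]] else
      st$v[of$i[k], of$j[k]]
    out[of$outlet_id[k]] <- out[of$outlet_id[k]] +
      val * of$sign[k] * ctx$dx
  }
  out
}

#' Run the built-in verification suite
#'
#' Static-droplet Laplace pressure, patch-advection conservation,
#' rotating-channel Coriolis skew, mesh-pair agreement, and the
#' stationary bifurcation split.
#'
#' @param checks character vector naming the checks to run (default
#'   all).
#' @param verbose print each result.
#' @return data.frame of results (one row per check) with an overall
#'   `"pass"` attribute.
#' @export
validate_solver <- function(checks = c("patch_advection", "laplace",
                                       "rotating_profile", "mesh_pair",
                                       "bifurcation_split"),
                            verbose = TRUE) {
  fns <- list(patch_advection = check_patch_advection,
              laplace = check_laplace,
              rotating_profile = check_rotating_profile,
              mesh_pair = check_mesh_pair,
              bifurcation_split = check_bifurcation_split)
  res <- list()
  for (nm in checks) {
    if (!nm %in% names(fns)) stop("unknown check: ", nm, call. = FALSE)
    r <- fns[[nm]]()
    attr(r, "profile") <- NULL
    res[[nm]] <- r
    if (verbose)
      message(sprintf("%-20s %s  value %.4g (target %.4g)  %s",
                      r$check, if (r$pass) "PASS" else "FAIL",
                      r$value, r$target, r$detail))
  }
  out <- do.call(rbind, res)
  attr(out, "pass") <- all(out$pass)
  out
}
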