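#' Volume-averaged mixture properties
#'
#' Arithmetic (volume-weighted) mixture density and viscosity:
#' rho = alpha_CP rho_CP + (1 - alpha_CP) rho_DP, and likewise for eta.
#'
#' @param alpha continuous-phase volume fraction (any numeric array).
#' @param fluids a [fluid_pair()].
#' @return list with `rho` and `eta`, same shape as `alpha`.
#' @export
mixture_properties <- function(alpha, fluids) {
  stopifnot(inherits(fluids, "fluid_pair"))
  list(rho = alpha * fluids$continuous$density +
         (1 - alpha) * fluids$dispersed$density,
       eta = alpha * fluids$continuous$viscosity +
         (1 - alpha) * fluids$dispersed$viscosity)
}

#' Interface curvature field
#'
#' kappa = -div(n) with n = grad(alpha_s)/|grad(alpha_s)| evaluated from
#' a smoothed volume fraction (smoothed-gradient curvature). Cells far
#' from the interface carry NA.
#'
#' @param alpha volume fraction (nx x ny).
#' @param grid a `vof_grid`.
#' @param smooth_passes smoothing passes before differentiation.
#' @param theta dispersed-phase wall contact angle in degrees, or NULL
#'   for a neutral (90 degree) wall. At a fluid-solid face belonging to
#'   a mixed cell, the wall-normal component of the interface normal is
#'   prescribed from the contact angle instead of being differenced
#'   across the wall, so wall wetting enters the interfacial force.
#' @return nx x ny matrix of curvature (1/m), NA away from the interface.
#' @export
interface_curvature <- function(alpha, grid, smooth_passes = 2L,
                                theta = NULL) {
  dx <- grid$dx; mask <- grid$mask
  nx <- grid$nx; ny <- grid$ny
  as <- smooth_cell_field(alpha, mask, smooth_passes)
  fm <- mask * 1
  mixed <- mask & alpha > 0.05 & alpha < 0.95
  cth <- if (is.null(theta)) 0 else cos(theta * pi / 180)
  # unit normals on faces from the smoothed field (fluid-fluid faces)
  gxf <- matrix(0, nx + 1, ny)   # d(as)/dx at x-faces
  gxf[2:nx, ] <- (as[2:nx, ] - as[1:(nx - 1), ]) / dx
  ffx <- matrix(FALSE, nx + 1, ny)
  ffx[2:nx, ] <- mask[2:nx, ] & mask[1:(nx - 1), ]
  gxf[!ffx] <- 0
  # tangential component at x-faces: average of cell-centered gy
  gc <- cell_gradient(as, mask, dx)
  gyf <- matrix(0, nx + 1, ny)
  gyf[2:nx, ] <- 0.5 * (gc$gy[2:nx, ] + gc$gy[1:(nx - 1), ])
  gyf[!ffx] <- 0
  nrmx <- sqrt(gxf^2 + gyf^2)
  nrmx[nrmx <= 1e-9 / dx] <- Inf
  nxf <- gxf / nrmx

  gyg <- matrix(0, nx, ny + 1)
  gyg[, 2:ny] <- (as[, 2:ny] - as[, 1:(ny - 1)]) / dx
  ffy <- matrix(FALSE, nx, ny + 1)
  ffy[, 2:ny] <- mask[, 2:ny] & mask[, 1:(ny - 1)]
  gyg[!ffy] <- 0
  gxg <- matrix(0, nx, ny + 1)
  gxg[, 2:ny] <- 0.5 * (gc$gx[, 2:ny] + gc$gx[, 1:(ny - 1)])
  gxg[!ffy] <- 0
  nrmy <- sqrt(gxg^2 + gyg^2)
  nrmy[nrmy <= 1e-9 / dx] <- Inf
  nyf <- gyg / nrmy

  # contact-angle prescription: at a wall face of a mixed cell the
  # normal component is -cos(theta) toward the solid (normal out of the
  # dispersed phase equals wall_normal*cos(theta) + tangent*sin(theta))
  if (!is.null(theta) && any(mixed)) {
    solidx <- rbind(TRUE, !mask, TRUE)    # (nx+2) x ny padded solid flags
    mixpad <- rbind(FALSE, mixed, FALSE)
    # x-face (i,j): cells i-1 (pad row i) and i (pad row i+1)
    sR <- solidx[2:(nx + 2), , drop = FALSE] & mixpad[1:(nx + 1), , drop = FALSE]
    sL <- solidx[1:(nx + 1), , drop = FALSE] & mixpad[2:(nx + 2), , drop = FALSE]
    nxf[sR] <- -cth          # solid on +x side: d-hat = +x, n.x = -cos(theta)
    nxf[sL] <- cth
    solidy <- cbind(TRUE, !mask, TRUE)
    mixpady <- cbind(FALSE, mixed, FALSE)
    sT <- solidy[, 2:(ny + 2), drop = FALSE] & mixpady[, 1:(ny + 1), drop = FALSE]
    sB <- solidy[, 1:(ny + 1), drop = FALSE] & mixpady[, 2:(ny + 2), drop = FALSE]
    nyf[sT] <- -cth
    nyf[sB] <- cth
  }

  kap <- -((nxf[2:(nx + 1), ] - nxf[1:nx, ]) +
             (nyf[, 2:(ny + 1)] - nyf[, 1:ny])) / dx
  gnorm <- sqrt(gc$gx^2 + gc$gy^2)
  kap[gnorm < 1e-3 / dx] <- NA_real_
  kap[!mask] <- NA_real_
  # interface-weighted averaging: damps the grid noise of the raw
  # divergence estimate (largest near contact lines) while preserving
  # the mean curvature of a resolved interface
  w <- alpha * (1 - alpha)
  w[!mask | is.na(kap)] <- 0
  k0 <- kap; k0[is.na(k0)] <- 0
  for (p in 1:2) {
    num <- k0 * w; den <- w
    for (djj in -1:1) for (dii in -1:1) {
      if (dii == 0 && djj == 0) next
      num <- num + shift2(k0 * w, dii, djj)
      den <- den + shift2(w, dii, djj)
    }
    k0 <- num / (den + (den == 0))
  }
  kap[!is.na(kap)] <- k0[!is.na(kap)]
  kap
}

#' Continuum-surface-force interfacial tension
#'
#' The density-weighted CSF body force
#' f = sigma * kappa * grad(alpha_CP) * rho / (0.5 (rho_CP + rho_DP)),
#' with kappa = -div(grad(alpha)/|grad(alpha)|) from the smoothed field.
#' Returns both the cell-centered force density (N/m^3) and the
#' staggered face accelerations `au`, `av` (m/s^2) used by the momentum
#' step; the face form divides by the phase-averaged reference density
#' so a static interface is discretely balanced by the pressure
#' gradient.
#'
#' @param alpha volume fraction (nx x ny).
#' @param grid a `vof_grid`.
#' @param fluids a [fluid_pair()].
#' @param smooth_passes smoothing passes for the curvature estimate.
#' @param theta wall contact angle (degrees) passed to
#'   [interface_curvature()]; defaults to the pair's dispersed-phase
#'   angle.
#' @return list: `fx`, `fy` (cell force density), `au`, `av` (face
#'   accelerations), `kappa`.
#' @export
surface_tension_force <- function(alpha, grid, fluids, smooth_passes = 2L,
                                  theta = fluids$theta_dispersed) {
  dx <- grid$dx; nx <- grid$nx; ny <- grid$ny
  sigma <- fluids$sigma
  rho_ref <- 0.5 * (fluids$continuous$density + fluids$dispersed$density)
  kap <- interface_curvature(alpha, grid, smooth_passes, theta = theta)
  kap0 <- ifelse(is.na(kap), 0, kap)
  has <- !is.na(kap)

  # face curvature: average of defined neighbor values
  au <- matrix(0, nx + 1, ny)
  kL <- kap0[1:(nx - 1), , drop = FALSE]; hL <- has[1:(nx - 1), , drop = FALSE]
  kR <- kap0[2:nx, , drop = FALSE];      hR <- has[2:nx, , drop = FALSE]
  den <- hL + hR
  kf <- (kL * hL + kR * hR) / pmax(den, 1)
  dadx <- (alpha[2:nx, , drop = FALSE] - alpha[1:(nx - 1), , drop = FALSE]) / dx
  au[2:nx, ] <- sigma * kf * dadx / rho_ref

  av <- matrix(0, nx, ny + 1)
  kB <- kap0[, 1:(ny - 1), drop = FALSE]; hB <- has[, 1:(ny - 1), drop = FALSE]
  kT <- kap0[, 2:ny, drop = FALSE];      hT <- has[, 2:ny, drop = FALSE]
  den <- hB + hT
  kfv <- (kB * hB + kT * hT) / pmax(den, 1)
  dady <- (alpha[, 2:ny, drop = FALSE] - alpha[, 1:(ny - 1), drop = FALSE]) / dx
  av[, 2:ny] <- sigma * kfv * dady / rho_ref

  # cell-centered force density (reported form)
  g <- cell_gradient(alpha, grid$mask, dx)
  mix <- mixture_properties(alpha, fluids)
  fx <- sigma * kap0 * g$gx * mix$rho / rho_ref
  fy <- sigma * kap0 * g$gy * mix$rho / rho_ref
  list(fx = fx, fy = fy, au = au, av = av, kappa = kap)
}
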