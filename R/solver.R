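# Solver context and the PISO-style two-phase time stepper.
#
# Staggered (MAC) arrangement: u on x-normal faces ((nx+1) x ny), v on
# y-normal faces (nx x (ny+1)), alpha / pressure / properties at cell
# centers. The discrete divergence is exact on faces, so the projection
# drives it to solver precision every step. Viscosity and the
# out-of-plane Hele-Shaw drag are treated implicitly (one sparse solve
# per velocity component per step); advection, interfacial tension and
# the rotating-frame body force are explicit.

# face status codes
FS_DEAD <- 0L; FS_WALL <- 1L; FS_INT <- 2L; FS_INLET <- 3L; FS_OUTLET <- 4L

#' Initialize a solver context for a case
#'
#' Rasterizes the case geometry, classifies faces, and pre-factorizes
#' the pressure-Poisson operator.
#'
#' @param case a `vof_case` from [build_case()].
#' @param dx override of the cell size (default: the case numerics).
#' @param body_forces include the rotating-frame body acceleration
#'   (disable only for frame-equivalence checks; with zero rotation the
#'   two paths are identical).
#' @return a `solver_ctx`.
#' @export
init_solver <- function(case, dx = NULL, body_forces = TRUE) {
  stopifnot(inherits(case, "vof_case"))
  if (is.null(dx)) dx <- case$numerics$dx
  grid <- rasterize_geometry(case$layout, dx)
  nx <- grid$nx; ny <- grid$ny
  mask <- grid$mask

  padx <- rbind(FALSE, mask, FALSE)
  fl <- padx[1:(nx + 1), , drop = FALSE]
  fr <- padx[2:(nx + 2), , drop = FALSE]
  ufstat <- matrix(FS_DEAD, nx + 1, ny)
  ufstat[fl & fr] <- FS_INT
  ubnd <- xor(fl, fr)
  ufstat[ubnd] <- FS_WALL
  pady <- cbind(FALSE, mask, FALSE)
  fb <- pady[, 1:(ny + 1), drop = FALSE]
  ft <- pady[, 2:(ny + 2), drop = FALSE]
  vfstat <- matrix(FS_DEAD, nx, ny + 1)
  vfstat[fb & ft] <- FS_INT
  vbnd <- xor(fb, ft)
  vfstat[vbnd] <- FS_WALL

  face_tag_u <- matrix(NA_character_, nx + 1, ny)
  face_sign_u <- matrix(NA_real_, nx + 1, ny)
  face_tag_v <- matrix(NA_character_, nx, ny + 1)
  face_sign_v <- matrix(NA_real_, nx, ny + 1)
  faces <- grid$faces
  fx <- faces$axis == "x"
  lin_u <- cbind(faces$i[fx], faces$j[fx])
  face_tag_u[lin_u] <- faces$tag[fx]
  face_sign_u[lin_u] <- faces$sign[fx]
  lin_v <- cbind(faces$i[!fx], faces$j[!fx])
  face_tag_v[lin_v] <- faces$tag[!fx]
  face_sign_v[lin_v] <- faces$sign[!fx]
  ufstat[!is.na(face_tag_u) & face_tag_u %in% c("inlet_cp", "inlet_dp")] <- FS_INLET
  ufstat[!is.na(face_tag_u) & face_tag_u == "outlet"] <- FS_OUTLET
  vfstat[!is.na(face_tag_v) & face_tag_v %in% c("inlet_cp", "inlet_dp")] <- FS_INLET
  vfstat[!is.na(face_tag_v) & face_tag_v == "outlet"] <- FS_OUTLET

  # per-port inlet face lists
  inports <- list()
  for (p in case$layout$ports) {
    if (!p$kind %in% c("inlet_cp", "inlet_dp")) next
    fsel <- faces[faces$port %in% p$name, , drop = FALSE]
    inports[[p$name]] <- list(
      name = p$name,
      phase = if (p$kind == "inlet_cp") "cp" else "dp",
      normal = p$normal,
      u_idx = cbind(fsel$i[fsel$axis == "x"], fsel$j[fsel$axis == "x"]),
      v_idx = cbind(fsel$i[fsel$axis == "y"], fsel$j[fsel$axis == "y"]))
  }

  # outlet faces and their interior neighbors (zero-gradient source)
  osel_u <- which(ufstat == FS_OUTLET)
  ou <- arrayInd(osel_u, dim(ufstat))
  ou_nb <- cbind(ou[, 1] - face_sign_u[osel_u], ou[, 2])
  osel_v <- which(vfstat == FS_OUTLET)
  ov <- arrayInd(osel_v, dim(vfstat))
  ov_nb <- cbind(ov[, 1], ov[, 2] - face_sign_v[osel_v])

  # pressure Poisson operator (constant coefficients, factorized once)
  cidx <- matrix(0L, nx, ny)
  cidx[mask] <- seq_len(sum(mask))
  ncell <- sum(mask)
  iu <- which(ufstat == FS_INT)
  uij <- arrayInd(iu, dim(ufstat))
  uL <- cidx[cbind(uij[, 1] - 1L, uij[, 2])]
  uR <- cidx[cbind(uij[, 1], uij[, 2])]
  iv <- which(vfstat == FS_INT)
  vij <- arrayInd(iv, dim(vfstat))
  vB <- cidx[cbind(vij[, 1], vij[, 2] - 1L)]
  vT <- cidx[cbind(vij[, 1], vij[, 2])]
  # outlet-face cells (Dirichlet phi = 0 at the face: diagonal 2)
  oc_u <- cidx[adjacent_fluid_cell_idx(ou, face_sign_u[osel_u], "x")]
  oc_v <- cidx[adjacent_fluid_cell_idx(ov, face_sign_v[osel_v], "y")]
  ii <- c(uL, uR, uL, uR, vB, vT, vB, vT, oc_u, oc_v)
  jj <- c(uL, uR, uR, uL, vB, vT, vT, vB, oc_u, oc_v)
  xx <- c(rep(1, 2 * length(uL)), rep(-1, 2 * length(uL)),
          rep(1, 2 * length(vB)), rep(-1, 2 * length(vB)),
          rep(2, length(oc_u) + length(oc_v)))
  if (!length(oc_u) && !length(oc_v)) {   # closed domain: pin the nullspace
    ii <- c(ii, 1L); jj <- c(jj, 1L); xx <- c(xx, 1)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx / dx^2,
                            dims = c(ncell, ncell))
  pchol <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)

  fluids <- case$fluids
  rho0 <- 0.5 * (fluids$continuous$density + fluids$dispersed$density)
  ctx <- list(case = case, grid = grid, dx = dx, nx = nx, ny = ny,
              mask = mask, H = grid$depth,
              ufstat = ufstat, vfstat = vfstat,
              face_tag_u = face_tag_u, face_sign_u = face_sign_u,
              face_tag_v = face_tag_v, face_sign_v = face_sign_v,
              inports = inports,
              outlet_u = ou, outlet_u_nb = ou_nb, outlet_u_sign = face_sign_u[osel_u],
              outlet_v = ov, outlet_v_nb = ov_nb, outlet_v_sign = face_sign_v[osel_v],
              cidx = cidx, ncell = ncell, pchol = pchol,
              pu = list(idx = iu, ij = uij, L = uL, R = uR),
              pv = list(idx = iv, ij = vij, B = vB, T = vT),
              pou = list(idx = osel_u, cell = oc_u),
              pov = list(idx = osel_v, cell = oc_v),
              rho0 = rho0, fluids = fluids,
              theta = fluids$theta_dispersed,
              hs = isTRUE(case$numerics$hs_friction),
              body_forces = body_forces,
              dp_open_t = 0,
              # face positions (disc coordinates) for the body force
              xu = outer(grid$x0 + (seq_len(nx + 1) - 1) * dx, rep(1, ny)),
              yu = outer(rep(1, nx + 1), grid$y0 + (seq_len(ny) - 0.5) * dx),
              xv = outer(grid$x0 + (seq_len(nx) - 0.5) * dx, rep(1, ny + 1)),
              yv = outer(rep(1, nx), grid$y0 + (seq_len(ny + 1) - 1) * dx))
  ctx$vs_u <- build_visc_struct("u", ctx)
  ctx$vs_v <- build_visc_struct("v", ctx)
  class(ctx) <- "solver_ctx"
  ctx
}

adjacent_fluid_cell_idx <- function(ij, sgn, axis) {
  if (!nrow(ij)) return(cbind(integer(0), integer(0)))
  if (axis == "x") cbind(ifelse(sgn > 0, ij[, 1] - 1L, ij[, 1]), ij[, 2])
  else cbind(ij[, 1], ifelse(sgn > 0, ij[, 2] - 1L, ij[, 2]))
}

#' Initial field state for a case
#'
#' The whole domain starts filled with continuous phase at rest; the
#' `static_droplet` case seeds a circular dispersed patch (sub-cell
#' resolved volume fractions).
#'
#' @param ctx a `solver_ctx`.
#' @return a `field_state`: alpha, u, v, p, t.
#' @export
init_state <- function(ctx) {
  nx <- ctx$nx; ny <- ctx$ny
  alpha <- matrix(1, nx, ny)
  pf <- ctx$case$layout$prefill
  if (!is.null(pf)) {
    g <- ctx$grid
    xc <- g$x0 + (seq_len(nx) - 0.5) * g$dx
    yc <- g$y0 + (seq_len(ny) - 0.5) * g$dx
    px <- rep(xc, times = ny); py <- rep(yc, each = nx)
    for (k in seq_len(nrow(pf))) {
      ins <- points_in_segment(px, py, pf[k, ])
      alpha[matrix(ins, nx, ny) & g$mask] <- 0
    }
  }
  if (!is.null(ctx$case$meta$droplet_radius)) {
    alpha <- init_alpha_circle(ctx$grid, ctx$case$meta$center,
                               ctx$case$meta$droplet_radius)
  }
  structure(list(alpha = alpha,
                 u = matrix(0, nx + 1, ny),
                 v = matrix(0, nx, ny + 1),
                 p = matrix(0, nx, ny), t = 0),
            class = "field_state")
}

#' Sub-cell resolved circular dispersed patch
#'
#' @param grid a `vof_grid`.
#' @param center circle center (m, disc coordinates).
#' @param radius circle radius (m).
#' @param nsub sub-samples per cell edge for the volume fraction.
#' @return alpha field (continuous-phase fraction; 0 inside the circle).
#' @export
init_alpha_circle <- function(grid, center, radius, nsub = 8L) {
  dx <- grid$dx
  off <- (seq_len(nsub) - 0.5) / nsub
  alpha <- matrix(1, grid$nx, grid$ny)
  xc <- grid$x0 + (seq_len(grid$nx) - 1) * dx
  yc <- grid$y0 + (seq_len(grid$ny) - 1) * dx
  # cells possibly intersecting the circle
  cand <- which(outer(abs(xc + dx / 2 - center[1]), abs(yc + dx / 2 - center[2]),
                      pmax) <= radius + dx, arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    px <- xc[i] + off * dx
    py <- yc[j] + off * dx
    inside <- outer(px - center[1], py - center[2],
                    function(a, b) a^2 + b^2) <= radius^2
    alpha[i, j] <- 1 - mean(inside)
  }
  alpha[!grid$mask] <- 1
  alpha
}

# inlet velocity BC application; returns list(u, v)
apply_velocity_bcs <- function(u, v, ctx, t, omega_abs) {
  u[ctx$ufstat == FS_DEAD | ctx$ufstat == FS_WALL] <- 0
  v[ctx$vfstat == FS_DEAD | ctx$vfstat == FS_WALL] <- 0
  case <- ctx$case
  for (p in ctx$inports) {
    U <- inlet_velocity(case, p$phase, omega_abs)
    if (p$phase == "dp" && t < ctx$dp_open_t) U <- 0
    if (nrow(p$u_idx)) u[p$u_idx] <- -U * p$normal[1]
    if (nrow(p$v_idx)) v[p$v_idx] <- -U * p$normal[2]
  }
  # outlet: zero-gradient from the interior, re-entrant flow clamped
  if (nrow(ctx$outlet_u)) {
    uval <- u[ctx$outlet_u_nb]
    re <- uval * ctx$outlet_u_sign < 0
    if (any(re)) { uval[re] <- 0; warn_reentrant() }
    u[ctx$outlet_u] <- uval
  }
  if (nrow(ctx$outlet_v)) {
    vval <- v[ctx$outlet_v_nb]
    re <- vval * ctx$outlet_v_sign < 0
    if (any(re)) { vval[re] <- 0; warn_reentrant() }
    v[ctx$outlet_v] <- vval
  }
  list(u = u, v = v)
}

warn_reentrant <- function() {
  if (!isTRUE(the$warned_reentrant)) {
    warning("re-entrant flow at an outlet clamped to zero", call. = FALSE)
    the$warned_reentrant <- TRUE
  }
}

# discrete divergence over fluid cells (matrix, 0 elsewhere)
divergence <- function(u, v, ctx) {
  nx <- ctx$nx; ny <- ctx$ny
  d <- (u[2:(nx + 1), , drop = FALSE] - u[1:nx, , drop = FALSE] +
          v[, 2:(ny + 1), drop = FALSE] - v[, 1:ny, drop = FALSE]) / ctx$dx
  d[!ctx$mask] <- 0
  d
}

# explicit momentum advection terms; second-order central in smooth
# regions (cell Peclet numbers here are well below the central-scheme
# stability bound), falling back to first-order upwind beside solid
# cells, where the central stencil would reach across a wall
advect_momentum <- function(u, v, ctx) {
  dx <- ctx$dx; nx <- ctx$nx; ny <- ctx$ny
  deadu <- ctx$ufstat == FS_DEAD
  uE <- shift2(u, -1, 0); uW <- shift2(u, 1, 0)
  uN <- shift2(u, 0, -1); uS <- shift2(u, 0, 1)
  # no-slip ghost for tangential neighbors in solid
  deadN <- shift2((deadu) * 1, 0, -1) > 0
  deadS <- shift2((deadu) * 1, 0, 1) > 0
  uN[deadN] <- -u[deadN]; uS[deadS] <- -u[deadS]
  deadE <- shift2((deadu) * 1, -1, 0) > 0
  deadW <- shift2((deadu) * 1, 1, 0) > 0
  vbar <- 0.25 * (shift2(rbind(v, 0), 0, 0)[1:(nx + 1), 1:ny] +
                    rbind(0, v)[1:(nx + 1), 1:ny] +
                    rbind(v, 0)[1:(nx + 1), 2:(ny + 1)] +
                    rbind(0, v)[1:(nx + 1), 2:(ny + 1)])
  adv_u <- u * (uE - uW) / (2 * dx) + vbar * (uN - uS) / (2 * dx)
  edge <- which(deadE | deadW | deadN | deadS)
  if (length(edge)) {
    pu <- u[edge] > 0
    pv <- vbar[edge] > 0
    upx <- (pu * (u[edge] - uW[edge]) + (!pu) * (uE[edge] - u[edge])) / dx
    upy <- (pv * (u[edge] - uS[edge]) + (!pv) * (uN[edge] - u[edge])) / dx
    adv_u[edge] <- u[edge] * upx + vbar[edge] * upy
  }

  deadv <- ctx$vfstat == FS_DEAD
  vE <- shift2(v, -1, 0); vW <- shift2(v, 1, 0)
  vN <- shift2(v, 0, -1); vS <- shift2(v, 0, 1)
  deadEv <- shift2((deadv) * 1, -1, 0) > 0
  deadWv <- shift2((deadv) * 1, 1, 0) > 0
  deadNv <- shift2((deadv) * 1, 0, -1) > 0
  deadSv <- shift2((deadv) * 1, 0, 1) > 0
  vE[deadEv] <- -v[deadEv]; vW[deadWv] <- -v[deadWv]
  ubar <- 0.25 * (cbind(u, 0)[1:nx, 1:(ny + 1)] +
                    cbind(0, u)[1:nx, 1:(ny + 1)] +
                    cbind(u, 0)[2:(nx + 1), 1:(ny + 1)] +
                    cbind(0, u)[2:(nx + 1), 1:(ny + 1)])
  adv_v <- ubar * (vE - vW) / (2 * dx) + v * (vN - vS) / (2 * dx)
  edgev <- which(deadEv | deadWv | deadNv | deadSv)
  if (length(edgev)) {
    pu <- ubar[edgev] > 0
    pv <- v[edgev] > 0
    upx <- (pu * (v[edgev] - vW[edgev]) + (!pu) * (vE[edgev] - v[edgev])) / dx
    upy <- (pv * (v[edgev] - vS[edgev]) + (!pv) * (vN[edgev] - v[edgev])) / dx
    adv_v[edgev] <- ubar[edgev] * upx + v[edgev] * upy
  }
  list(au = adv_u, av = adv_v, vbar = vbar, ubar = ubar)
}

# precompute the assembly structure of the implicit viscous system for
# one velocity component: active faces, per-direction neighbor
# classification, and the slot map into a fixed sparse pattern
build_visc_struct <- function(comp, ctx) {
  if (comp == "u") { stat <- ctx$ufstat; nx1 <- ctx$nx + 1; ny1 <- ctx$ny }
  else { stat <- ctx$vfstat; nx1 <- ctx$nx; ny1 <- ctx$ny + 1 }
  act <- stat == FS_INT
  nact <- sum(act)
  if (!nact) return(NULL)
  rank <- matrix(0L, nx1, ny1); rank[act] <- seq_len(nact)
  lin <- which(act)
  ij <- arrayInd(lin, c(nx1, ny1))
  dirs <- list(E = c(1L, 0L), W = c(-1L, 0L), N = c(0L, 1L), S = c(0L, -1L))
  per_dir <- lapply(dirs, function(d) {
    ni <- ij[, 1] + d[1]; nj <- ij[, 2] + d[2]
    inb <- ni >= 1L & ni <= nx1 & nj >= 1L & nj <= ny1
    nlin <- rep(NA_integer_, nact)
    nlin[inb] <- (nj[inb] - 1L) * nx1 + ni[inb]
    nst <- rep(FS_DEAD, nact)
    nst[inb] <- stat[nlin[inb]]
    list(unk = nst == FS_INT,
         known = nst == FS_WALL | nst == FS_INLET | nst == FS_OUTLET,
         ghost = nst == FS_DEAD,
         nbr_rank = ifelse(nst == FS_INT, rank[pmax(nlin, 1L)], 0L),
         nbr_lin = nlin)
  })
  ii <- unlist(lapply(per_dir, function(p) seq_len(nact)[p$unk]))
  jj <- unlist(lapply(per_dir, function(p) p$nbr_rank[p$unk]))
  ii <- c(ii, seq_len(nact)); jj <- c(jj, seq_len(nact))
  skel <- Matrix::sparseMatrix(i = ii, j = jj, x = seq_along(ii),
                               dims = c(nact, nact))
  list(comp = comp, nact = nact, lin = lin, per_dir = per_dir,
       pattern = skel, perm = skel@x,
       env = new.env(parent = emptyenv()))
}

# per-step face/corner viscosity coefficient matrices for one component
visc_coefs <- function(comp, eta, rho, ctx) {
  dx <- ctx$dx
  if (comp == "u") {
    etaL <- rbind(0, eta); etaR <- rbind(eta, 0)
    rhoL <- rbind(0, rho); rhoR <- rbind(rho, 0)
    mL <- rbind(FALSE, ctx$mask); mR <- rbind(ctx$mask, FALSE)
    den <- pmax(mL + mR, 1)
    cmask <- ctx$mask * 1
    csum <- cbind(0, cmask) + cbind(cmask, 0)
    ceta <- cbind(0, eta) + cbind(eta, 0)
    cden <- rbind(0, csum) + rbind(csum, 0)
    cor_eta <- (rbind(0, ceta) + rbind(ceta, 0)) / pmax(cden, 1)
    ny1 <- ctx$ny
    list(cE = etaR / dx^2, cW = etaL / dx^2,
         cS = cor_eta[, 1:ny1, drop = FALSE] / dx^2,
         cN = cor_eta[, 2:(ny1 + 1), drop = FALSE] / dx^2,
         etaF = (etaL + etaR) / den, rhoF = (rhoL + rhoR) / den)
  } else {
    etaL <- cbind(0, eta); etaR <- cbind(eta, 0)
    rhoL <- cbind(0, rho); rhoR <- cbind(rho, 0)
    mL <- cbind(FALSE, ctx$mask); mR <- cbind(ctx$mask, FALSE)
    den <- pmax(mL + mR, 1)
    cmask <- ctx$mask * 1
    csum <- rbind(0, cmask) + rbind(cmask, 0)
    ceta <- rbind(0, eta) + rbind(eta, 0)
    cden <- cbind(0, csum) + cbind(csum, 0)
    cor_eta <- (cbind(0, ceta) + cbind(ceta, 0)) / pmax(cden, 1)
    nx1 <- ctx$nx
    list(cN = etaR / dx^2, cS = etaL / dx^2,
         cW = cor_eta[1:nx1, , drop = FALSE] / dx^2,
         cE = cor_eta[2:(nx1 + 1), , drop = FALSE] / dx^2,
         etaF = (etaL + etaR) / den, rhoF = (rhoL + rhoR) / den)
  }
}

# implicit viscous + Hele-Shaw solve for one velocity component; the
# sparse pattern and symbolic factorization are reused across steps
solve_viscous <- function(comp, ustar, eta, rho, dt, ctx) {
  vs <- if (comp == "u") ctx$vs_u else ctx$vs_v
  if (is.null(vs)) return(ustar)
  co <- visc_coefs(comp, eta, rho, ctx)
  lin <- vs$lin
  dval <- co$rhoF[lin] / dt
  if (ctx$hs) dval <- dval + 12 * co$etaF[lin] / ctx$H^2
  bval <- co$rhoF[lin] * ustar[lin] / dt
  offv <- list()
  for (nm in c("E", "W", "N", "S")) {
    p <- vs$per_dir[[nm]]
    cf <- co[[paste0("c", nm)]][lin]
    dval <- dval + cf
    dval[p$ghost] <- dval[p$ghost] + cf[p$ghost]
    if (any(p$known))
      bval[p$known] <- bval[p$known] +
        cf[p$known] * ustar[p$nbr_lin[p$known]]
    offv[[nm]] <- -cf[p$unk]
  }
  vals <- c(unlist(offv), dval)
  A <- vs$pattern
  A@x <- vals[vs$perm]
  As <- Matrix::forceSymmetric(A)
  if (is.null(vs$env$chol)) vs$env$chol <- Matrix::Cholesky(As, LDL = FALSE)
  else vs$env$chol <- Matrix::update(vs$env$chol, As)
  sol <- Matrix::solve(vs$env$chol, bval)
  out <- ustar
  out[lin] <- as.numeric(sol)
  out
}

#' One PISO-style pressure-velocity step
#'
#' Explicit predictor (advection + body forces + interfacial tension),
#' implicit viscous/Hele-Shaw solve, then `n_corrector` (>= 2)
#' pressure-correction sweeps enforcing the divergence constraint, with
#' no-slip walls, fixed inlet velocities and zero-gauge outlets.
#'
#' @param state a `field_state`.
#' @param ctx a `solver_ctx`.
#' @param dt time step (s).
#' @param st surface-tension face accelerations (list with `au`, `av`)
#'   or NULL.
#' @param mix mixture property fields from [mixture_properties()] (NULL
#'   to compute from the state).
#' @return list: `state` (updated velocities/pressure), `p_residual`
#'   (rms divergence after correction, 1/s), `div_max`.
#' @export
piso_step <- function(state, ctx, dt, st = NULL, mix = NULL) {
  if (is.null(mix)) mix <- mixture_properties(state$alpha, ctx$fluids)
  tn <- state$t + dt
  om <- omega_at(ctx$case$rotation, tn)
  u <- state$u; v <- state$v
  bc <- apply_velocity_bcs(u, v, ctx, tn, abs(om$omega))
  u <- bc$u; v <- bc$v

  adv <- advect_momentum(u, v, ctx)
  ustar <- u - dt * adv$au
  vstar <- v - dt * adv$av
  if (!is.null(st)) {
    ustar <- ustar + dt * st$au
    vstar <- vstar + dt * st$av
  }
  if (ctx$body_forces && (om$omega != 0 || om$domega != 0)) {
    rhoL <- rbind(0, mix$rho); rhoR <- rbind(mix$rho, 0)
    mL <- rbind(FALSE, ctx$mask); mR <- rbind(ctx$mask, FALSE)
    rho_u <- (rhoL + rhoR) / pmax(mL + mR, 1)
    su <- body_acceleration(cbind(as.numeric(ctx$xu), as.numeric(ctx$yu)),
                            cbind(as.numeric(u), as.numeric(adv$vbar)),
                            om$omega, om$domega)
    ustar <- ustar + dt * matrix(su[, 1], ctx$nx + 1, ctx$ny) * rho_u / ctx$rho0
    rhoB <- cbind(0, mix$rho); rhoT <- cbind(mix$rho, 0)
    mB <- cbind(FALSE, ctx$mask); mT <- cbind(ctx$mask, FALSE)
    rho_v <- (rhoB + rhoT) / pmax(mB + mT, 1)
    sv <- body_acceleration(cbind(as.numeric(ctx$xv), as.numeric(ctx$yv)),
                            cbind(as.numeric(adv$ubar), as.numeric(v)),
                            om$omega, om$domega)
    vstar <- vstar + dt * matrix(sv[, 2], ctx$nx, ctx$ny + 1) * rho_v / ctx$rho0
  }
  bc <- apply_velocity_bcs(ustar, vstar, ctx, tn, abs(om$omega))
  ustar <- solve_viscous("u", bc$u, mix$eta, mix$rho, dt, ctx)
  vstar <- solve_viscous("v", bc$v, mix$eta, mix$rho, dt, ctx)
  bc <- apply_velocity_bcs(ustar, vstar, ctx, tn, abs(om$omega))
  u <- bc$u; v <- bc$v

  phi_tot <- matrix(0, ctx$nx, ctx$ny)
  ncorr <- ctx$case$numerics$n_corrector
  for (sweep in seq_len(ncorr)) {
    dv <- divergence(u, v, ctx)
    rhs <- -dv[ctx$mask] / dt
    phi <- as.numeric(Matrix::solve(ctx$pchol, rhs))
    phim <- matrix(0, ctx$nx, ctx$ny)
    phim[ctx$mask] <- phi
    # correct interior faces
    gi <- (phim[cbind(ctx$pu$ij[, 1], ctx$pu$ij[, 2])] -
             phim[cbind(ctx$pu$ij[, 1] - 1L, ctx$pu$ij[, 2])]) / ctx$dx
    u[ctx$pu$idx] <- u[ctx$pu$idx] - dt * gi
    gj <- (phim[cbind(ctx$pv$ij[, 1], ctx$pv$ij[, 2])] -
             phim[cbind(ctx$pv$ij[, 1], ctx$pv$ij[, 2] - 1L)]) / ctx$dx
    v[ctx$pv$idx] <- v[ctx$pv$idx] - dt * gj
    # correct outlet faces (phi = 0 at the face)
    if (length(ctx$pou$idx))
      u[ctx$pou$idx] <- u[ctx$pou$idx] +
        dt * 2 * phim[cbind(adjacent_fluid_cell_idx(ctx$outlet_u, ctx$outlet_u_sign, "x"))] *
        ctx$outlet_u_sign / ctx$dx
    if (length(ctx$pov$idx))
      v[ctx$pov$idx] <- v[ctx$pov$idx] +
        dt * 2 * phim[cbind(adjacent_fluid_cell_idx(ctx$outlet_v, ctx$outlet_v_sign, "y"))] *
        ctx$outlet_v_sign / ctx$dx
    phi_tot <- phi_tot + phim
  }
  dv <- divergence(u, v, ctx)
  state$u <- u; state$v <- v
  state$p <- phi_tot * ctx$rho0
  state$t <- tn
  list(state = state,
       p_residual = sqrt(mean(dv[ctx$mask]^2)),
       div_max = max(abs(dv)))
}

#' Capillary time-step bound
#'
#' Explicit interfacial-tension stability limit
#' sqrt((rho_CP + rho_DP) dx^3 / (4 pi sigma)).
#'
#' @param fluids a [fluid_pair()].
#' @param dx cell size (m).
#' @return time in s.
#' @export
capillary_dt <- function(fluids, dx) {
  sqrt((fluids$continuous$density + fluids$dispersed$density) * dx^3 /
         (4 * pi * fluids$sigma))
}

#' Advance the solution by one time step
#'
#' Chooses the time step (advective CFL, capillary limit, user cap;
#' fixed 1e-7 s in strict mode), advects the volume fraction, updates
#' mixture properties and forces, and performs the PISO step, in that
#' order.
#'
#' @param state a `field_state`.
#' @param ctx a `solver_ctx`.
#' @param two_phase force the two-phase path (default: auto-detect).
#' @return list: `state`, `diag` (one-row data.frame of step
#'   diagnostics).
#' @export
step <- function(state, ctx, two_phase = NULL) {
  num <- ctx$case$numerics
  dx <- ctx$dx
  if (is.null(two_phase))
    two_phase <- any(state$alpha[ctx$mask] < 1) ||
      any(vapply(ctx$inports, function(p) p$phase == "dp", TRUE))
  vmax <- max(abs(state$u), abs(state$v), 1e-12)
  dt <- min(num$cfl * dx / vmax, num$dt_max)
  if (two_phase)
    dt <- min(dt, num$capillary_safety * capillary_dt(ctx$fluids, dx))
  if (num$strict_dt) dt <- 1e-7

  bflux <- c(inlet_cp = 0, inlet_dp = 0, outlet = 0)
  nsub <- 0L
  if (two_phase) {
    adv <- advect_alpha(state$alpha, state$u, state$v, dt, ctx,
                        sweep_first = if (the$sweep_flip %||% FALSE) "y" else "x",
                        theta = ctx$theta)
    the$sweep_flip <- !(the$sweep_flip %||% FALSE)
    state$alpha <- adv$alpha
    bflux <- adv$boundary_dispersed
    nsub <- adv$nsub
  }
  mix <- mixture_properties(state$alpha, ctx$fluids)
  st <- if (two_phase)
    surface_tension_force(state$alpha, ctx$grid, ctx$fluids,
                          num$smooth_passes) else NULL
  res <- piso_step(state, ctx, dt, st = st, mix = mix)
  state <- res$state
  if (!all(is.finite(state$u)) || !all(is.finite(state$v)) ||
      !all(is.finite(state$alpha)))
    stop(sprintf("NaN detected at t = %.6g s; aborting (last good state at t = %.6g)",
                 state$t, state$t - dt), call. = FALSE)
  vdisp <- sum(1 - state$alpha[ctx$mask]) * dx^2 * ctx$H
  diag <- data.frame(t = state$t, dt = dt,
                     max_cfl = vmax * dt / dx,
                     p_residual = res$p_residual, div_max = res$div_max,
                     dispersed_volume = vdisp,
                     flux_inlet_dp = bflux[["inlet_dp"]],
                     flux_outlet = bflux[["outlet"]],
                     adv_subcycles = nsub)
  list(state = state, diag = diag)
}
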