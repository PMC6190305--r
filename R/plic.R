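# PLIC (piecewise-linear interface construction) in planar 2D: each
# mixed cell carries a line m . x = d (m the interface normal pointing
# out of the continuous phase, unit length, cell-local coordinates in
# [0,1]^2) positioned so that the sub-cell region {m . x <= d} has area
# exactly equal to the continuous-phase fraction alpha_CP.

#' Area fraction of a rectangle cut by a half-plane
#'
#' Fraction of the axis-aligned rectangle `[x0,x1] x [y0,y1]` lying in
#' the half-plane `mx*x + my*y <= d`. Vectorized over all arguments;
#' exact closed form (the standard corner formula).
#'
#' @param mx,my half-plane normal components (need not be normalized).
#' @param d half-plane offset.
#' @param x0,x1,y0,y1 rectangle bounds.
#' @return fraction in `[0, 1]`.
#' @keywords internal
#' @export
rect_cut_fraction <- function(mx, my, d, x0 = 0, x1 = 1, y0 = 0, y1 = 1) {
  n <- max(length(mx), length(my), length(d), length(x0), length(x1),
           length(y0), length(y1))
  mx <- rep_len(mx, n); my <- rep_len(my, n); d <- rep_len(d, n)
  x0 <- rep_len(x0, n); x1 <- rep_len(x1, n)
  y0 <- rep_len(y0, n); y1 <- rep_len(y1, n)
  # reflect so both normal components are >= 0
  neg <- mx < 0
  if (any(neg)) {
    tmp <- x0[neg]
    x0[neg] <- -x1[neg]; x1[neg] <- -tmp
    mx[neg] <- -mx[neg]
  }
  neg <- my < 0
  if (any(neg)) {
    tmp <- y0[neg]
    y0[neg] <- -y1[neg]; y1[neg] <- -tmp
    my[neg] <- -my[neg]
  }
  w <- x1 - x0; h <- y1 - y0
  dd <- d - mx * x0 - my * y0
  a <- mx * w; b <- my * h
  scale <- pmax(a + b, .Machine$double.xmin)
  tiny <- (a + b) * 1e-14
  out <- numeric(n)
  degen <- a <= tiny & b <= tiny          # normal ~ 0: all-or-nothing
  out[degen] <- as.numeric(dd[degen] >= 0)
  ax0 <- !degen & a <= tiny               # vertical-independent: d vs my*y
  out[ax0] <- pmin(pmax(dd[ax0] / b[ax0], 0), 1)
  ay0 <- !degen & b <= tiny & a > tiny
  out[ay0] <- pmin(pmax(dd[ay0] / a[ay0], 0), 1)
  gen <- !degen & !ax0 & !ay0
  if (any(gen)) {
    dg <- dd[gen]; ag <- a[gen]; bg <- b[gen]
    pp <- function(z) pmax(z, 0)^2
    out[gen] <- (pp(dg) - pp(dg - ag) - pp(dg - bg) + pp(dg - ag - bg)) /
      (2 * ag * bg)
  }
  pmin(pmax(out, 0), 1)
}

# invert the cut: offset d on the unit cell such that the cut fraction
# equals alpha; exact closed form (piecewise quadratic/linear in d)
plic_offset <- function(mx, my, alpha) {
  px <- abs(mx); py <- abs(my)
  s <- px + py
  s[s == 0] <- 1
  m1 <- px / s; m2 <- py / s
  m <- pmin(m1, m2); M <- pmax(m1, m2)
  a <- pmin(pmax(alpha, 0), 1)
  flip <- a > 0.5
  a2 <- a
  a2[flip] <- 1 - a[flip]
  quad <- a2 <= m / (2 * M) & m > 0
  dd <- a2 * M + m / 2
  dd[quad] <- sqrt(2 * a2[quad] * m[quad] * M[quad])
  dd[flip] <- 1 - dd[flip]
  dd * s - pmax(0, -mx) - pmax(0, -my)
}

# 3x3 kernel smoothing of a cell field, renormalized over fluid cells
# (solid neighbors carry no weight); `passes` applications
smooth_cell_field <- function(f, mask, passes = 2L) {
  if (passes < 1L) return(f)
  w <- matrix(0, nrow(f), ncol(f)); w[mask] <- 1
  fv <- f; fv[!mask] <- 0
  kern <- c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16
  for (p in seq_len(passes)) {
    num <- kern[5] * fv; den <- kern[5] * w
    kk <- 0L
    for (djj in -1:1) for (dii in -1:1) {
      kk <- kk + 1L
      if (dii == 0 && djj == 0) next
      num <- num + kern[kk] * shift2(fv, dii, djj)
      den <- den + kern[kk] * shift2(w, dii, djj)
    }
    fv <- num / (den + (den == 0))
    fv[!mask] <- 0
  }
  fv[!mask] <- f[!mask]
  fv
}

# shift a matrix by (di, dj), padding with 0
shift2 <- function(m, di, dj) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx, ny)
  xs <- max(1, 1 + di):min(nx, nx + di)
  ys <- max(1, 1 + dj):min(ny, ny + dj)
  out[xs, ys] <- m[xs - di, ys - dj]
  out
}

# cell-centered gradient of a field with zero-gradient closure at
# solid/domain boundaries; returns list(gx, gy)
cell_gradient <- function(f, mask, dx) {
  fe <- shift2(f, -1, 0); fw <- shift2(f, 1, 0)
  fn <- shift2(f, 0, -1); fs <- shift2(f, 0, 1)
  me <- shift2(mask * 1, -1, 0) > 0; mw <- shift2(mask * 1, 1, 0) > 0
  mn <- shift2(mask * 1, 0, -1) > 0; ms <- shift2(mask * 1, 0, 1) > 0
  fe[!me] <- f[!me]; fw[!mw] <- f[!mw]
  fn[!mn] <- f[!mn]; fs[!ms] <- f[!ms]
  he <- me + mw                 # effective span in cells
  hv <- mn + ms
  gx <- (fe - fw) / (pmax(he, 1) * dx)   # numerator is 0 where span is 0
  gy <- (fn - fs) / (pmax(hv, 1) * dx)
  list(gx = gx, gy = gy)
}

#' Reconstruct the PLIC interface
#'
#' Computes Youngs-type interface normals from the gradient of a
#' smoothed volume-fraction field, applies the wall contact-angle
#' prescription in wall-adjacent mixed cells, and positions the line in
#' every mixed cell so its cut area reproduces the cell's volume
#' fraction to 1e-10.
#'
#' @param alpha continuous-phase volume fraction field (nx x ny matrix).
#' @param grid a `vof_grid` (or a solver context).
#' @param theta dispersed-phase contact angle in degrees, or NULL to
#'   skip the wall prescription.
#' @param smooth_passes smoothing passes for the normal estimate.
#' @param prev previous-step interface, used as a fallback for
#'   degenerate normals (|grad alpha| ~ 0 in a mixed cell).
#' @param eps mixed-cell tolerance: cells with `eps < alpha < 1 - eps`
#'   carry an interface.
#' @return object of class `plic_interface`: mixed-cell indices, unit
#'   normals (pointing out of the continuous phase) and line offsets in
#'   cell-local coordinates.
#' @export
reconstruct_plic <- function(alpha, grid, theta = NULL, smooth_passes = 2L,
                             prev = NULL, eps = 1e-8) {
  mask <- grid$mask
  mixed <- which(mask & alpha > eps & alpha < 1 - eps)
  if (!length(mixed))
    return(structure(list(idx = integer(0), mx = numeric(0), my = numeric(0),
                          d = numeric(0), alpha = numeric(0),
                          dim = dim(alpha)),
                     class = "plic_interface"))
  as <- smooth_cell_field(alpha, mask, smooth_passes)
  g <- cell_gradient(as, mask, 1)   # cell-local units
  # normal out of the continuous phase: -grad(alpha_CP)
  mx <- -g$gx[mixed]; my <- -g$gy[mixed]
  nrm <- sqrt(mx^2 + my^2)
  degen <- nrm < 1e-12
  if (any(degen)) {
    if (!isTRUE(the$warned_degenerate_normal)) {
      warning("degenerate interface normal in mixed cell; using fallback normal",
              call. = FALSE)
      the$warned_degenerate_normal <- TRUE
    }
    mx[degen] <- 1; my[degen] <- 0; nrm[degen] <- 1
    if (!is.null(prev) && length(prev$idx)) {
      hit <- match(mixed[degen], prev$idx)
      ok <- !is.na(hit)
      mx[degen][ok] <- prev$mx[hit[ok]]
      my[degen][ok] <- prev$my[hit[ok]]
      nrm[degen][ok] <- 1
    }
  }
  mx <- mx / nrm; my <- my / nrm
  iface <- structure(list(idx = mixed, mx = mx, my = my,
                          d = numeric(length(mixed)),
                          alpha = alpha[mixed], dim = dim(alpha)),
                     class = "plic_interface")
  if (!is.null(theta)) iface <- apply_contact_angle(iface, grid, theta,
                                                    resolve = FALSE)
  iface$d <- plic_offset(iface$mx, iface$my, iface$alpha)
  iface
}

#' Impose the static wall contact angle on interface normals
#'
#' In mixed cells adjacent to a wall, replaces the interface normal with
#' the ghost-normal prescription `n = n_wall * cos(theta) + t_wall *
#' sin(theta)`, where `theta` is the static contact angle measured
#' through the dispersed phase, `n_wall` the wall normal into the fluid,
#' and `t_wall` the wall tangent oriented away from the dispersed phase
#' (taken from the current normal's tangential component). A neutral
#' angle of 90 degrees leaves the wall-tangential component unchanged
#' and zeroes the wall-normal component.
#'
#' @param iface a `plic_interface`.
#' @param grid a `vof_grid`.
#' @param theta contact angle in degrees, strictly inside (0, 180).
#' @param resolve re-solve the line offsets after rotating the normals
#'   (default TRUE).
#' @return the modified `plic_interface`.
#' @export
apply_contact_angle <- function(iface, grid, theta, resolve = TRUE) {
  if (theta <= 0 || theta >= 180)
    stop("theta must lie strictly between 0 and 180 degrees", call. = FALSE)
  if (!length(iface$idx)) return(iface)
  mask <- grid$mask
  nx <- nrow(mask); ny <- ncol(mask)
  ij <- arrayInd(iface$idx, dim(mask))
  # wall normal into the fluid: sum of directions toward solid, negated
  solid_at <- function(di, dj) {
    ii <- ij[, 1] + di; jj <- ij[, 2] + dj
    inb <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny
    out <- rep(TRUE, nrow(ij))       # outside the domain counts as solid
    out[inb] <- !mask[cbind(ii[inb], jj[inb])]
    out
  }
  sE <- solid_at(1, 0); sW <- solid_at(-1, 0)
  sN <- solid_at(0, 1); sS <- solid_at(0, -1)
  wx <- ifelse(sE, -1, 0) + ifelse(sW, 1, 0)
  wy <- ifelse(sN, -1, 0) + ifelse(sS, 1, 0)
  at_wall <- (wx != 0 | wy != 0)
  if (!any(at_wall)) return(iface)
  wn <- sqrt(wx^2 + wy^2); wn[!at_wall] <- 1
  wx <- wx / wn; wy <- wy / wn
  # current normal out of the dispersed phase is -(mx, my)
  nxo <- -iface$mx; nyo <- -iface$my
  tdot <- nxo * (-wy) + nyo * wx       # component along wall tangent (-wy, wx)
  tsgn <- ifelse(tdot >= 0, 1, -1)
  tx <- -wy * tsgn; ty <- wx * tsgn
  th <- theta * pi / 180
  newx <- wx * cos(th) + tx * sin(th)  # normal out of dispersed phase
  newy <- wy * cos(th) + ty * sin(th)
  iface$mx[at_wall] <- -newx[at_wall]
  iface$my[at_wall] <- -newy[at_wall]
  if (resolve) iface$d <- plic_offset(iface$mx, iface$my, iface$alpha)
  iface
}

#' Evaluate the cut fraction a PLIC interface assigns to each mixed cell
#'
#' Used to verify the reconstruction invariant (cut area equals the
#' volume fraction).
#'
#' @param iface a `plic_interface`.
#' @return numeric vector of cut fractions, one per mixed cell.
#' @export
plic_cut_fractions <- function(iface) {
  if (!length(iface$idx)) return(numeric(0))
  rect_cut_fraction(iface$mx, iface$my, iface$d)
}
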