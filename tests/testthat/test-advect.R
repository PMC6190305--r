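# geometric interface transport: conservation, boundedness, and accuracy
# against independent references

make_box_grid <- function(nx, ny, dx = 1e-5) {
  g <- list(dx = dx, nx = nx, ny = ny, x0 = 0, y0 = 0,
            mask = matrix(TRUE, nx, ny), depth = 1e-4)
  class(g) <- "vof_grid"
  g
}

test_that("uniform fields are invariant under any advection velocity", {
  g <- make_box_grid(16, 16)
  alpha <- matrix(1, 16, 16)
  u <- matrix(0.03, 17, 16); v <- matrix(-0.02, 16, 17)
  out <- advect_alpha(alpha, u, v, 1e-4, g)
  expect_equal(out$alpha, alpha)
})

test_that("a translated square patch lands where it should with exact volume", {
  r <- check_patch_advection()
  expect_true(r$pass)
  expect_lt(r$value, 1e-8)
})

test_that("Zalesak slotted-disc revolution conserves volume and beats upwind", {
  n <- 64
  g <- make_box_grid(n, n, dx = 1 / n)
  xc <- (seq_len(n) - 0.5) / n
  yc <- xc
  # slotted disc: radius 0.22 at (0.5, 0.68), slot width 0.1
  inside <- function(x, y) {
    d <- sqrt((x - 0.5)^2 + (y - 0.68)^2) <= 0.22
    slot <- abs(x - 0.5) <= 0.05 & y <= 0.68 + 0.05
    d & !slot
  }
  sub <- 4
  off <- (seq_len(sub) - 0.5) / sub
  alpha0 <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    px <- (i - 1 + off) / n
    py <- (j - 1 + off) / n
    alpha0[i, j] <- 1 - mean(outer(px, py, inside))
  }
  om <- 2 * pi     # one revolution per unit time about the domain center
  xf <- (seq_len(n + 1) - 1) / n
  u <- -om * outer(rep(1, n + 1), yc - 0.5)
  v <- om * outer(xc - 0.5, rep(1, n + 1))
  vmax <- max(abs(u), abs(v))
  dt <- 0.4 / (n * vmax)
  nstep <- ceiling(1 / dt)
  dt <- 1 / nstep

  alpha <- alpha0
  for (s in seq_len(nstep)) {
    out <- advect_alpha(alpha, u, v, dt, g,
                        sweep_first = if (s %% 2) "x" else "y")
    alpha <- out$alpha
    expect_lt(out$bound_excess, 1e-7)
  }
  v0 <- sum(1 - alpha0); v1 <- sum(1 - alpha)
  expect_lt(abs(v1 - v0) / v0, 1e-8)

  # first-order upwind baseline run by the same harness
  upwind <- alpha0
  for (s in seq_len(nstep)) {
    f_e <- ifelse(u[2:(n + 1), ] > 0, upwind, rbind(upwind[-1, ], 1)) *
      u[2:(n + 1), ]
    f_w <- ifelse(u[1:n, ] > 0, rbind(1, upwind[-n, ]), upwind) * u[1:n, ]
    f_n <- ifelse(v[, 2:(n + 1)] > 0, upwind, cbind(upwind[, -1], 1)) *
      v[, 2:(n + 1)]
    f_s <- ifelse(v[, 1:n] > 0, cbind(1, upwind[, -n]), upwind) * v[, 1:n]
    upwind <- upwind - dt * n * (f_e - f_w + f_n - f_s)
    upwind <- pmin(pmax(upwind, 0), 1)
  }
  shape_err <- function(a) sum(abs((a < 0.5) - (alpha0 < 0.5))) / sum(alpha0 < 0.5)
  expect_lt(shape_err(alpha), shape_err(upwind))
  expect_lt(shape_err(alpha), 0.5)
})

test_that("advection sub-cycles when the face Courant number is too large", {
  g <- make_box_grid(16, 16)
  alpha <- matrix(1, 16, 16); alpha[6:9, 6:9] <- 0
  u <- matrix(0.1, 17, 16); v <- matrix(0, 16, 17)
  out <- advect_alpha(alpha, u, v, 2e-4, g)   # Courant 2.0
  expect_gte(out$nsub, 4)
  expect_lt(abs(sum(1 - out$alpha) - 16) / 16, 1e-8)
})
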