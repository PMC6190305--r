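test_that("mixture properties are the printed volume-weighted averages", {
  pair <- builtin_fluid_pair("device")
  m1 <- mixture_properties(matrix(1, 2, 2), pair)
  expect_equal(unique(as.numeric(m1$rho)), 908.7)
  expect_equal(unique(as.numeric(m1$eta)), 0.0643)
  m0 <- mixture_properties(matrix(0, 2, 2), pair)
  expect_equal(unique(as.numeric(m0$rho)), 997)
  expect_equal(unique(as.numeric(m0$eta)), 0.001003)
  mh <- mixture_properties(0.5, pair)
  expect_equal(mh$rho, 952.85)
  expect_equal(mh$eta, 0.0326515)
  a <- matrix(runif(64), 8, 8)
  mm <- mixture_properties(a, pair)
  expect_true(all(mm$rho >= 908.7 & mm$rho <= 997))
  expect_true(all(mm$eta >= 0.001003 & mm$eta <= 0.0643))
})

test_that("surface tension force vanishes away from interfaces", {
  case <- build_case("static_droplet")
  g <- rasterize_geometry(case$layout, 5e-6)
  st <- surface_tension_force(matrix(1, g$nx, g$ny), g, case$fluids)
  expect_equal(max(abs(st$au)), 0)
  expect_equal(max(abs(st$av)), 0)
  expect_equal(max(abs(st$fx)), 0)
})

test_that("a static droplet carries the Young-Laplace pressure jump", {
  r <- check_laplace(cells_per_radius = 20, n_steps = 60, tol = 0.05)
  expect_true(r$pass)
  expect_equal(r$value, 285.2, tolerance = 0.05)
})

test_that("spurious currents shrink under grid refinement", {
  spur <- vapply(c(10, 20), function(cpr) {
    case <- build_case("static_droplet",
                       list(numerics = list(dx = 50e-6 / cpr)))
    ctx <- init_solver(case)
    state <- init_state(ctx)
    for (k in 1:40) state <- spindrop::step(state, ctx)$state
    max(abs(state$u), abs(state$v))
  }, 0)
  expect_lt(spur[2], spur[1])
})

test_that("pressure-driven channel flow matches the plane-Poiseuille profile", {
  case <- build_case("patch_advection",
                     list(inlets = list(cp = list(mode = "fixed",
                                                  velocity = 0.02)),
                          numerics = list(hs_friction = FALSE)))
  run <- run_case(case, t_end = 3e-3, snapshot_dt = 3e-4,
                  stop_when_steady = TRUE, steady_tol = 1e-6)
  st <- run$snapshots[[length(run$snapshots)]]
  g <- run$ctx$grid
  i <- round(g$nx / 2)
  rows <- which(g$mask[i, ])
  expect_length(rows, 20)
  u <- 0.5 * (st$u[i, rows] + st$u[i + 1, rows])
  y <- (seq_along(rows) - 0.5) / length(rows)
  ua <- 6 * mean(u) * y * (1 - y)
  expect_lt(max(abs(u - ua)) / max(ua), 0.02)
  expect_equal(mean(u), 0.02, tolerance = 1e-6)   # mass conservation
  expect_lt(max(run$diagnostics$div_max), 1e-8)
})

test_that("zero forcing and zero inflow stay identically at rest", {
  case <- build_case("static_droplet")
  case$meta$droplet_radius <- NULL    # no interface, no forcing
  ctx <- init_solver(case, dx = 10e-6)
  state <- init_state(ctx)
  for (k in 1:3) state <- spindrop::step(state, ctx)$state
  expect_equal(max(abs(state$u)), 0)
  expect_equal(max(abs(state$v)), 0)
})

test_that("wall droplets relax toward their equilibrium contact-angle caps", {
  # geometry/wetting oracle: a droplet seeded as a half-circle (90 deg)
  # on the floor must spread under a wetting angle and retract under a
  # hydrophobic one, approaching the circular-cap base/height ratio
  # 2 sin(theta) / (1 - cos(theta)). A light continuous phase is used
  # so relaxation fits a test-scale run; the equilibrium shape is
  # viscosity-independent.
  cap_run <- function(theta, nsteps) {
    case <- build_case("static_droplet",
      list(numerics = list(dx = 3e-6, hs_friction = FALSE),
           meta = list(droplet_radius = 36e-6, center = c(100e-6, 0))))
    case$layout <- toy_layout("box", size = 200e-6)
    case$fluids <- fluid_pair(fluid_properties(908.7, 5e-3),
                              fluid_properties(997, 1.003e-3),
                              0.01426, theta)
    ctx <- init_solver(case)
    state <- init_state(ctx)
    for (k in seq_len(nsteps)) state <- spindrop::step(state, ctx)$state
    disp <- 1 - state$alpha; disp[!ctx$mask] <- 0
    jbot <- min(which(colSums(disp) > 0.5))
    base <- sum(disp[, jbot])
    height <- sum(colSums(disp) > 0.5)
    base / height
  }
  cap_target <- function(theta) {
    th <- theta * pi / 180
    2 * sin(th) / (1 - cos(th))
  }
  # wetting case: matches the spherical-cap formula within 10%
  r60 <- cap_run(60, 2200)
  expect_equal(r60, cap_target(60), tolerance = 0.1)
  # hydrophobic case (the PDMS/water angle): the contact line retracts
  # from the seeded 90-degree shape toward the cap value; coarse-grid
  # contact-line pinning stops short of the exact ratio, so the check
  # is one-sided
  r112 <- cap_run(112, 1400)
  expect_lt(r112, 0.9 * 2)          # clearly below the seeded ratio 2
  expect_gt(r112, cap_target(112) * 0.9)
})

test_that("the time step respects the capillary stability bound", {
  case <- device_mini_case(omega = 150, t_end = 1)
  ctx <- init_solver(case)
  state <- init_state(ctx)
  bound <- capillary_dt(case$fluids, ctx$dx)
  expect_equal(bound,
               sqrt((908.7 + 997) * ctx$dx^3 / (4 * pi * 0.01426)))
  for (k in 1:5) {
    res <- spindrop::step(state, ctx)
    state <- res$state
    expect_lte(res$diag$dt, bound)
  }
})

test_that("dispersed volume change matches the boundary fluxes each step", {
  case <- device_mini_case(omega = 150, t_end = 1)
  ctx <- init_solver(case)
  state <- init_state(ctx)
  vols <- numeric(0); fl <- numeric(0)
  for (k in 1:25) {
    res <- spindrop::step(state, ctx)
    state <- res$state
    vols <- c(vols, res$diag$dispersed_volume)
    fl <- c(fl, res$diag$flux_inlet_dp + res$diag$flux_outlet)
  }
  vtot <- vols[length(vols)]
  err <- abs(diff(vols) + fl[-1]) / vtot
  expect_lt(max(err), 1e-8)
  # cumulative drift over the window
  expect_lt(abs(vols[length(vols)] - vols[1] + sum(fl[-1])) / vtot, 1e-5)
})

test_that("volume fractions stay bounded through a two-phase run", {
  case <- device_mini_case(omega = 150, t_end = 1)
  ctx <- init_solver(case)
  state <- init_state(ctx)
  for (k in 1:25) state <- spindrop::step(state, ctx)$state
  expect_gte(min(state$alpha), 0)
  expect_lte(max(state$alpha), 1)
})
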