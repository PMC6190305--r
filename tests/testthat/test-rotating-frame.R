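test_that("the spin-up schedule evaluates as a linear ramp", {
  sch <- rotation_schedule(150, t_ramp = 0.01)
  mid <- omega_at(sch, 0.005)
  expect_equal(mid$omega, 75)
  expect_equal(mid$domega, 15000)
  late <- omega_at(sch, 1)
  expect_equal(late$omega, 150)
  expect_equal(late$domega, 0)
  vec <- omega_at(sch, c(0, 0.005, 0.02))
  expect_equal(vec$omega, c(0, 75, 150))
  # step start: full speed for t > 0, acceleration reported as zero
  assign("warned_step_ramp", NULL, envir = spindrop:::the)
  expect_warning(st <- omega_at(rotation_schedule(150, t_ramp = 0), 1e-9),
                 "step")
  expect_equal(st$omega, 150)
  expect_equal(st$domega, 0)
  cw <- omega_at(rotation_schedule(150, 0.01, sense = -1), 1)
  expect_equal(cw$omega, -150)
})

test_that("body acceleration reproduces centrifugal and Coriolis anchors", {
  a <- body_acceleration(c(0.032, 0), c(0, 0), 150, 0)
  expect_equal(a[1, 1], 150^2 * 0.032)   # 720 m/s^2, radially outward
  expect_equal(a[1, 2], 0)

  # pure Coriolis: magnitude 2 Omega U, normal to the throughflow and
  # opposite the rotation sense
  a <- body_acceleration(c(0, 0), c(0.01, 0), 150, 0)
  expect_equal(a[1, 1], 0)
  expect_equal(a[1, 2], -2 * 150 * 0.01)
  expect_equal(sqrt(sum(a^2)), 3.0)
})

test_that("body acceleration equals a component-wise cross-product oracle", {
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  set.seed(7)
  for (k in 1:25) {
    r <- runif(2, -0.05, 0.05); v <- runif(2, -0.2, 0.2)
    om <- runif(1, -300, 300); dom <- runif(1, -1e4, 1e4)
    W <- c(0, 0, om); dW <- c(0, 0, dom)
    r3 <- c(r, 0); v3 <- c(v, 0)
    ref <- -cross3(W, cross3(W, r3)) - 2 * cross3(W, v3) - cross3(dW, r3)
    got <- body_acceleration(r, v, om, dom)
    expect_equal(as.numeric(got), ref[1:2], tolerance = 1e-14)
  }
})

test_that("Coriolis term is orthogonal to the velocity", {
  set.seed(11)
  for (k in 1:20) {
    v <- runif(2, -1, 1); om <- runif(1, -200, 200)
    a <- body_acceleration(c(0, 0), v, om, 0)   # Coriolis only at r = 0
    dot <- abs(sum(a[1, ] * v))
    expect_lt(dot, 1e-12 * sqrt(sum(v^2)) * max(sqrt(sum(a^2)), 1e-30))
  }
})

test_that("with zero rotation the rotating-frame path is bitwise identical to the plain solver", {
  case <- build_case("patch_advection",
                     list(inlets = list(cp = list(mode = "fixed",
                                                  velocity = 0.02))))
  run_rot <- run_case(case, t_end = 5e-5, snapshot_dt = 5e-5,
                      body_forces = TRUE)
  run_plain <- run_case(case, t_end = 5e-5, snapshot_dt = 5e-5,
                        body_forces = FALSE)
  s1 <- run_rot$snapshots[[length(run_rot$snapshots)]]
  s2 <- run_plain$snapshots[[length(run_plain$snapshots)]]
  expect_identical(s1$u, s2$u)
  expect_identical(s1$v, s2$v)
  expect_identical(s1$p, s2$p)
})
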