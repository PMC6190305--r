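test_that("dimensionless numbers match direct arithmetic and published anchors", {
  # Ca: velocity inverted from the benchmark caption value Ca = 0.16
  expect_equal(capillary_number(0.0622, 0.0729, 0.02833), 0.160,
               tolerance = 1e-2)
  expect_equal(capillary_number(0.5, 0, 0.01), 0)
  expect_equal(capillary_number(0.0643, 0.01, 0.01426),
               0.0643 * 0.01 / 0.01426)
  expect_equal(capillary_number(0.0643, 0.01, 0.01426), 0.0451,
               tolerance = 1e-3)
  expect_error(capillary_number(0.06, 0.1, 0), "sigma")

  expect_equal(weber_number(997, 133.3e-6, 0, 0.01426), 0)
  expect_equal(weber_number(997, 133.3e-6, 0.1, 0.01426),
               997 * 133.3e-6 * 0.01 / 0.01426)
  expect_equal(weber_number(997, 133.3e-6, 0.1, 0.01426), 0.0932,
               tolerance = 1e-3)
  expect_equal(weber_number(997, 133.3e-6, 0.2, 0.01426) /
                 weber_number(997, 133.3e-6, 0.1, 0.01426), 4)
  expect_error(weber_number(997, -1, 0.1, 0.01), "L")

  # Bond number of the device at full speed (figure-caption anchor 0.08)
  Dh <- hydraulic_diameter(200e-6, 100e-6)
  bo <- bond_number(997 - 908.7, 0.032, 150, Dh, 0.01426)
  expect_equal(round(bo, 2), 0.08)
  expect_equal(bond_number(88.3, 0.032, 0, Dh, 0.01426), 0)
  expect_equal(bond_number(-88.3, 0.032, 150, Dh, 0.01426), bo)  # |drho|

  # the 24 -> 40 Hz scaling factor, consistent with the printed pair
  ratio <- bond_number(96, 0.03, from_hz(40), Dh, 0.02833) /
    bond_number(96, 0.03, from_hz(24), Dh, 0.02833)
  expect_equal(ratio, (40 / 24)^2)
  expect_equal(ratio, 2.78, tolerance = 2e-3)
  expect_equal(0.25 / 0.09, ratio, tolerance = 0.02 / ratio)

  # centrifugal pumping velocity
  expect_equal(mean_channel_velocity(133.33e-6, 908.7, 0, 0.02, 1e-3,
                                     0.0643, 1e-3), 0)
  expect_equal(mean_channel_velocity(133.33e-6, 908.7, 150, 0.02, 1, 0.0643, 1),
               3.53e-3, tolerance = 1e-3)
  u1 <- mean_channel_velocity(1e-4, 1000, 100, 0.02, 1e-3, 0.01, 1e-3)
  expect_equal(mean_channel_velocity(1e-4, 1000, 100, 0.04, 1e-3, 0.01, 1e-3),
               2 * u1)           # linear in rbar
  expect_equal(mean_channel_velocity(1e-4, 1000, 200, 0.02, 1e-3, 0.01, 1e-3),
               4 * u1)           # quadratic in Omega
  expect_error(mean_channel_velocity(1e-4, 1000, 100, 0.02, 1e-3, 0.01, 0),
               "c")

  # Rossby number per phase
  expect_equal(rossby_number(997, 150, 133.33e-6, 1.003e-3), 2.65,
               tolerance = 1e-2)
  expect_equal(rossby_number(908.7, 150, 133.33e-6, 0.0643), 0.0377,
               tolerance = 1e-2)
  expect_equal(rossby_number(997, 0, 133.33e-6, 1.003e-3), 0)
  expect_error(rossby_number(997, 150, 133.33e-6, 0), "eta")
})

test_that("regime and outlet classification follow the stated rules", {
  expect_equal(classify_dripping_jetting(0.01, 0.01), "dripping")
  expect_equal(classify_dripping_jetting(10, 10), "jetting")
  # ties go to jetting (strict inequality for dripping)
  expect_equal(classify_dripping_jetting(0.1, 0.5, ca_star = 0.1), "jetting")
  expect_equal(classify_dripping_jetting(0.05, 1, we_star = 1), "jetting")
  expect_error(classify_dripping_jetting(0.1, 0.1, ca_star = 0), "threshold")

  expect_equal(classify_outlet(0.0377), "A")
  expect_equal(classify_outlet(2.65), "B")
  expect_equal(classify_outlet(0), "A")
  expect_error(classify_outlet(-1), "Ro")
})

test_that("Bo is monotone in its drivers and Ro is radius-independent", {
  Dh <- hydraulic_diameter(200e-6, 100e-6)
  om <- seq(10, 300, length.out = 8)
  expect_true(all(diff(bond_number(88.3, 0.03, om, Dh, 0.0143)) > 0))
  rr <- seq(0.01, 0.05, length.out = 8)
  expect_true(all(diff(bond_number(88.3, rr, 150, Dh, 0.0143)) > 0))
  LL <- seq(5e-5, 5e-4, length.out = 8)
  expect_true(all(diff(bond_number(88.3, 0.03, 150, LL, 0.0143)) > 0))
  dd <- seq(10, 200, length.out = 8)
  expect_true(all(diff(bond_number(dd, 0.03, 150, Dh, 0.0143)) > 0))

  case <- build_case("device")
  ros <- vapply(seq(0.01, 0.05, length.out = 6), function(r)
    dimensionless_set(case, r = r)$Ro_dispersed, 0)
  expect_equal(max(ros) - min(ros), 0)
})

test_that("the groups are invariant under consistent unit rescaling", {
  # scale lengths by kL, time by kT, mass by kM and rescale every input
  # by its dimensions: the dimensionless numbers must not change
  set.seed(42)
  for (rep in 1:5) {
    kL <- runif(1, 0.2, 5); kT <- runif(1, 0.2, 5); kM <- runif(1, 0.2, 5)
    eta <- 0.06; v <- 0.03; sig <- 0.015; rho <- 950; L <- 1.3e-4
    om <- 120; r <- 0.03
    sc <- list(eta = kM / (kL * kT), v = kL / kT, sig = kM / kT^2,
               rho = kM / kL^3, L = kL, om = 1 / kT, r = kL)
    expect_equal(capillary_number(eta * sc$eta, v * sc$v, sig * sc$sig),
                 capillary_number(eta, v, sig))
    expect_equal(weber_number(rho * sc$rho, L * sc$L, v * sc$v, sig * sc$sig),
                 weber_number(rho, L, v, sig))
    expect_equal(bond_number(88 * sc$rho, r * sc$r, om * sc$om, L * sc$L,
                             sig * sc$sig),
                 bond_number(88, r, om, L, sig))
    expect_equal(rossby_number(rho * sc$rho, om * sc$om, L * sc$L,
                               eta * sc$eta),
                 rossby_number(rho, om, L, eta))
  }
})

test_that("per-phase Rossby classification separates the device phases", {
  case <- build_case("device")
  for (om in c(100, 150)) {
    d <- dimensionless_set(case, omega = om)
    expect_equal(d$outlet_dispersed, "B")
    expect_equal(d$outlet_continuous, "A")
  }
  sw <- sweep_numbers(case, c(100, 150))
  expect_equal(sw$outlet_dispersed, c("B", "B"))
  expect_equal(sw$outlet_continuous, c("A", "A"))
})
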