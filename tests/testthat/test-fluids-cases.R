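test_that("fluid and channel constructors validate and derive fields", {
  f <- fluid_properties(908.7, from_cP(64.3))
  expect_equal(f$viscosity, 0.0643)
  expect_error(fluid_properties(-1, 0.01), "density")
  expect_error(fluid_properties(1000, 0), "viscosity")
  pair <- builtin_fluid_pair("device")
  expect_equal(delta_rho(pair), 997 - 908.7)
  expect_equal(delta_rho(pair, signed = TRUE), 997 - 908.7)
  expect_error(fluid_pair(f, f, 0.01, theta_dispersed = 190), "theta")

  ch <- rect_channel(200e-6, 100e-6, 25e-3)
  expect_equal(ch$Dh, 2 * 200e-6 * 100e-6 / (300e-6), tolerance = 1e-15)
  expect_equal(ch$Dh, 133.33e-6, tolerance = 1e-4)
  expect_equal(hydraulic_diameter(ch), ch$Dh)
})

test_that("built-in cases carry the published operating values", {
  v24 <- build_case("validation_24Hz")
  expect_equal(v24$fluids$continuous$viscosity, 0.0622)
  expect_equal(v24$fluids$continuous$density, 909)
  expect_equal(v24$fluids$dispersed$viscosity, 0.00109)
  expect_equal(v24$fluids$dispersed$density, 1005)
  expect_equal(v24$fluids$sigma, 0.02833)
  expect_equal(v24$rotation$omega_final, 2 * pi * 24)
  expect_equal(v24$layout$channel$width, 660e-6)
  expect_equal(v24$layout$channel$height, 200e-6)
  expect_equal(v24$layout$meta$W_constriction, 376e-6)
  expect_equal(v24$layout$meta$junction_angle, 80)

  dev <- build_case("device")
  expect_equal(dev$fluids$continuous$viscosity, 0.0643)
  expect_equal(dev$fluids$continuous$density, 908.7)
  expect_equal(dev$fluids$dispersed$viscosity, 0.001003)
  expect_equal(dev$fluids$dispersed$density, 997)
  expect_equal(dev$fluids$sigma, 0.01426)
  expect_equal(dev$fluids$theta_dispersed, 112)
  expect_equal(dev$fluids$theta_continuous, 26.44)
  expect_equal(dev$layout$channel$width, 200e-6)
  expect_equal(dev$layout$channel$height, 100e-6)
  expect_equal(dev$numerics$dx, 20e-6)

  sd <- build_case("static_droplet")
  expect_equal(sd$meta$droplet_radius, 50e-6)
  expect_equal(sd$rotation$omega_final, 0)
})

test_that("case overrides are validated and errors name the field", {
  expect_error(build_case("nonsense"), "unknown case_id")
  expect_error(build_case("device", list(numerix = list(dx = 1))), "numerix")
  expect_error(build_case("device", list(numerics = list(dz = 1))), "dz")
  expect_error(build_case("device",
                          list(inlets = list(cp = list(mode = "fixed",
                                                       velocity = -2)))),
               "velocity")
  c2 <- build_case("device", list(numerics = list(dx = 1e-5)))
  expect_equal(c2$numerics$dx, 1e-5)
  expect_equal(c2$numerics$cfl, build_case("device")$numerics$cfl)
})

test_that("case serialization round-trips field-by-field", {
  for (id in c("device", "validation_24Hz", "static_droplet")) {
    case <- build_case(id)
    path <- tempfile(fileext = ".yaml")
    write_case(case, path)
    back <- read_case(path)
    expect_equal(back, case, tolerance = 1e-12)
    unlink(path)
  }
})

test_that("rasterization resolves channels and refuses coarse grids", {
  lay <- toy_layout("channel", size = 1e-3, W = 200e-6)
  g <- rasterize_geometry(lay, 20e-6)
  # 200 um channel at 20 um: 10 cells across at mid-length
  i <- round(g$nx / 2)
  expect_equal(sum(g$mask[i, ]), 10)
  expect_error(rasterize_geometry(lay, 60e-6), "4 cells")
  expect_error(rasterize_geometry(lay, 60e-6), "5e-05")

  vg <- rasterize_geometry(validation_layout(length = 3e-3), 20e-6)
  meta <- validation_layout()$meta
  i <- round((meta$r_junction + 1.5e-3 - vg$x0) / vg$dx)
  expect_equal(sum(vg$mask[i, ]), 33)   # 660 um wide droplet channel
})

test_that("rasterized device is flood-fill connected from the inlet to both outlets", {
  lay <- device_layout()
  g <- rasterize_geometry(lay, 20e-6)
  conn <- grid_connectivity(g)
  expect_true(conn$all_reached)
  expect_true(all(conn$outlets_reached[c("A", "B")]))

  # independent flood-fill oracle (breadth-first on the mask)
  mask <- g$mask
  faces <- g$faces
  seed <- faces[faces$tag == "inlet_cp", ][1, ]
  start <- if (seed$sign > 0) c(seed$i - 1, seed$j) else c(seed$i, seed$j)
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- matrix(as.integer(start), ncol = 2)
  visited[queue] <- TRUE
  while (nrow(queue)) {
    nbrs <- rbind(cbind(queue[, 1] + 1L, queue[, 2]),
                  cbind(queue[, 1] - 1L, queue[, 2]),
                  cbind(queue[, 1], queue[, 2] + 1L),
                  cbind(queue[, 1], queue[, 2] - 1L))
    ok <- nbrs[, 1] >= 1 & nbrs[, 1] <= nrow(mask) &
      nbrs[, 2] >= 1 & nbrs[, 2] <= ncol(mask)
    nbrs <- nbrs[ok, , drop = FALSE]
    new <- nbrs[mask[nbrs] & !visited[nbrs], , drop = FALSE]
    new <- unique(new)
    visited[new] <- TRUE
    queue <- new
  }
  expect_true(all(visited[mask]))
  out_faces <- faces[faces$tag == "outlet", ]
  oc <- cbind(ifelse(out_faces$axis == "x" & out_faces$sign > 0,
                     out_faces$i - 1, out_faces$i),
              ifelse(out_faces$axis == "y" & out_faces$sign > 0,
                     out_faces$j - 1, out_faces$j))
  expect_true(all(visited[oc]))
})

test_that("rasterization at dx and dx/2 converges (mask mismatch is O(dx))", {
  lay <- validation_layout(length = 2e-3)
  a1 <- rasterize_geometry(lay, 20e-6)
  a2 <- rasterize_geometry(lay, 10e-6)
  area1 <- sum(a1$mask) * a1$dx^2
  area2 <- sum(a2$mask) * a2$dx^2
  expect_lt(abs(area1 - area2) / area2, 0.05)
  a3 <- rasterize_geometry(lay, 5e-6)
  area3 <- sum(a3$mask) * a3$dx^2
  # refinement shrinks the area mismatch roughly linearly in dx
  expect_lt(abs(area2 - area3), abs(area1 - area2) + 1e-12)
})

test_that("device layout rejects inconsistent radial positions", {
  expect_error(device_layout(junction_radii = c(28e-3, 24e-3)), "increasing")
  expect_error(device_layout(junction_radii = c(24e-3, 60e-3)), "disc_radius")
})
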