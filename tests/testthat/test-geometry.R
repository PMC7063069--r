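test_that("beam frame transform is rigid, centred on the isocenter, and invertible", {
  b <- beam_geometry(0, SAD = 1000, isocenter = c(12, -7, 30))
  expect_equal(world_to_beam(c(12, -7, 30), b), c(0, 0, 0))
  p <- c(12, -7, 30) + c(0, 0, 10)
  expect_equal(sqrt(sum(world_to_beam(p, b)^2)), 10)
  set.seed(42)
  for (g in c(0, 37.5, 90, 180, 271)) {
    bb <- beam_geometry(g, SAD = 1000, isocenter = c(5, 5, 5))
    pts <- matrix(stats::rnorm(30, sd = 100), ncol = 3)
    expect_lt(max(abs(beam_to_world(world_to_beam(pts, bb), bb) - pts)), 1e-9)
  }
})

test_that("gantry 0 points the beam downward and rotation is about the patient axis", {
  b0 <- beam_geometry(0, SAD = 1000)
  ## source above the isocenter along +Y world
  expect_equal(beam_to_world(c(0, 0, 1000), b0), c(0, 1000, 0))
  b90 <- beam_geometry(90, SAD = 1000)
  expect_equal(beam_to_world(c(0, 0, 1000), b90), c(1000, 0, 0), tolerance = 1e-12)
  ## world Z (patient axis) is the in-plane beam y for every gantry angle
  for (g in c(0, 72, 144)) {
    expect_equal(world_to_beam(c(0, 0, 25), beam_geometry(g, SAD = 1000))[2], 25,
                 tolerance = 1e-12)
  }
})

test_that("gantry angles differing by a full turn give identical transforms", {
  b1 <- beam_geometry(359.999999, SAD = 1000)
  b2 <- beam_geometry(0 - 1e-6 + 360, SAD = 1000)
  expect_equal(ifp:::beam_axes(b1), ifp:::beam_axes(b2))
  ## and the rotation is 360-periodic in the analytic sense
  a1 <- ifp:::beam_axes(beam_geometry(73.2))
  g2 <- 73.2 + 360
  b3 <- beam_geometry(73.2)
  b3$gantry_angle <- g2   # bypass the range check to compose the full turn
  expect_equal(ifp:::beam_axes(b3), a1, tolerance = 1e-12)
})

test_that("divergent projection matches the closed form and its edge cases", {
  expect_equal(project_point(c(10, -5, 0), 1500), c(10, -5, 0))
  expect_equal(project_point(c(10, 0, 500), 1000), c(20, 0, 0))
  expect_equal(project_point(c(0, 0, 300), 1000), c(0, 0, 0))
  expect_error(project_point(c(1, 1, 1000), 1000), class = "ifp_geometry_error")
  expect_error(project_point(c(1, 1, 1200), 1000), class = "ifp_geometry_error")
})

test_that("projection is the identity at z = 0, magnifies for z > 0 and shrinks for z < 0", {
  set.seed(7)
  for (i in 1:200) {
    p <- c(stats::runif(2, -80, 80), stats::runif(1, -200, 500))
    pr <- project_point(p, 1000)
    r_in <- sqrt(sum(p[1:2]^2)); r_out <- sqrt(sum(pr[1:2]^2))
    if (p[3] > 0) expect_gte(r_out, r_in)
    if (p[3] < 0) expect_lte(r_out, r_in)
    if (abs(p[3]) > 1e-12 && r_in > 1e-12) expect_gt(abs(r_out - r_in), 0)
  }
})

test_that("projected deformation vectors are endpoint differences", {
  expect_equal(project_vector(c(10, 0, 250), c(12, 0, 250), 1000),
               c(12 * 1000 / 750 - 10 * 1000 / 750, 0), tolerance = 1e-12)
  expect_equal(project_vector(c(10, 0, 250), c(12, 0, 250), 1000),
               c(2.6667, 0), tolerance = 1e-3)
  expect_equal(project_vector(c(0, 0, 0), c(0, 0, 100), 2000), c(0, 0))
  expect_equal(project_vector(c(3, 4, 120), c(3, 4, 120), 1000), c(0, 0))
})

test_that("pixel rays join the source to the plane point and obey similar triangles", {
  b <- beam_geometry(0, SAD = 1000)
  r0 <- pixel_ray(c(0, 0), 1000, b)
  ## central axis passes through the isocenter
  t_iso <- 1000
  expect_lt(max(abs(r0$source + t_iso * r0$direction - b$isocenter)), 1e-9)
  r <- pixel_ray(c(10, 0), 1000, b)
  ## beam-frame z = 0 crossing at (10, 0, 0); z = 500 crossing at (5, 0, 500)
  hit_at_z <- function(r, z, b) {
    sb <- world_to_beam(r$source, b); db <- ifp:::rotate_to_beam(r$direction, b)
    tt <- (z - sb[3]) / db[3]
    sb + tt * db
  }
  expect_equal(hit_at_z(r, 0, b), c(10, 0, 0), tolerance = 1e-9)
  expect_equal(hit_at_z(r, 500, b), c(5, 0, 500), tolerance = 1e-9)
})

test_that("projecting any point on a pixel's ray recovers the pixel coordinates", {
  set.seed(11)
  for (i in 1:50) {
    b <- beam_geometry(stats::runif(1, 0, 360), SAD = 1000,
                       isocenter = stats::rnorm(3, sd = 20))
    px <- stats::runif(2, -60, 60)
    r <- pixel_ray(px, b$SAD, b)
    tt <- stats::runif(1, 300, 1400)   # stay in front of the source
    p_world <- r$source + tt * r$direction
    pr <- project_point(world_to_beam(p_world, b), b$SAD)
    expect_lt(max(abs(pr[1:2] - px)), 1e-6)
  }
})

test_that("invalid beam parameters are rejected", {
  expect_error(beam_geometry(-1), class = "ifp_input_error")
  expect_error(beam_geometry(360), class = "ifp_input_error")
  expect_error(beam_geometry(0, SAD = 0), class = "ifp_input_error")
  expect_error(beam_geometry(0, collimator_angle = 10), class = "ifp_input_error")
})
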