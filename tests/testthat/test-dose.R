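water_box <- function(n = 24, s = 5, density = 1) {
  g <- grid3d(c(n, n, n), c(s, s, s), origin = rep(-(n - 1) * s / 2, 3))
  volume3d(g, array(density, g$shape))
}

open_field <- function(value = 1, n = 20, s = 5) {
  plane <- plane_grid(c(n, n), c(s, s))
  fluence_grid(plane, matrix(value, n, n))
}

test_that("with no attenuation the central-axis dose follows the inverse square law", {
  vol <- water_box(25, 5)                      # odd: a voxel column sits on the axis
  b <- beam_geometry(0, SAD = 1000)
  dose <- compute_dose(list(list(beam = b, fluence = open_field())), vol,
                       list(mu_per_mm = 0))
  ys <- vol$grid$origin[2] + (0:24) * 5
  axis_dose <- dose$values[13, , 13]
  expected <- (1000 / (1000 - ys))^2           # beam z equals world y at gantry 0
  expect_equal(axis_dose, expected, tolerance = 1e-9)
})

test_that("in homogeneous water the depth-dose ratio is exp(-mu d) times inverse square", {
  vol <- water_box(25, 5)
  b <- beam_geometry(0, SAD = 1000)
  mu <- 0.004
  dose <- compute_dose(list(list(beam = b, fluence = open_field())), vol,
                       list(mu_per_mm = mu))
  ys <- vol$grid$origin[2] + (0:24) * 5
  axis_dose <- dose$values[13, , 13]
  entry <- max(ys) + 2.5                       # upper bounding face (beam from +y)
  depth <- entry - ys
  expected <- exp(-mu * depth) * (1000 / (1000 - ys))^2
  expect_equal(axis_dose, expected, tolerance = 1e-9)
  ## pairwise depth ratio form
  expect_equal(axis_dose[5] / axis_dose[15],
               exp(-mu * (depth[5] - depth[15])) *
                 (1000 - ys[15])^2 / (1000 - ys[5])^2, tolerance = 1e-9)
})

test_that("two opposed beams on a symmetric phantom give a symmetric dose", {
  vol <- water_box(16, 5)
  f <- open_field(n = 12, s = 5)
  dose <- compute_dose(list(list(beam = beam_geometry(0, SAD = 1000), fluence = f),
                            list(beam = beam_geometry(180, SAD = 1000), fluence = f)),
                       vol, list(mu_per_mm = 0.004))
  ## symmetry about the isocenter plane perpendicular to the beam axis (y)
  expect_equal(dose$values, dose$values[, 16:1, ], tolerance = 1e-6)
})

test_that("the dose engine is exactly linear in the fluence", {
  vol <- water_box(12, 5, density = 0.8)
  b <- beam_geometry(72, SAD = 1000)
  plane <- plane_grid(c(10, 10), c(5, 5))
  set.seed(9)
  m1 <- matrix(stats::runif(100), 10, 10)
  m2 <- matrix(stats::runif(100), 10, 10)
  p <- list(mu_per_mm = 0.005)
  d1 <- compute_dose(list(list(beam = b, fluence = fluence_grid(plane, m1))), vol, p)
  d2 <- compute_dose(list(list(beam = b, fluence = fluence_grid(plane, m2))), vol, p)
  d12 <- compute_dose(list(list(beam = b, fluence = fluence_grid(plane, m1 + m2))), vol, p)
  expect_equal(d12$values, d1$values + d2$values, tolerance = 1e-12)
  expect_error(compute_dose(list(), vol, p), class = "ifp_input_error")
})

test_that("DVH metrics agree with direct counting and sorting oracles", {
  g <- unit_grid(10, 2)
  roi <- roi_mask(g, array(TRUE, g$shape), "all")
  ## uniform dose
  u <- volume3d(g, array(42, g$shape), role = "dose")
  m <- dvh_metrics(u, roi, prescription = 42)
  expect_equal(m$D95, 42); expect_equal(m$D5, 42); expect_equal(m$mean, 42)
  expect_equal(m$HI, 1); expect_equal(m$V100_pct, 100)
  ## half at 0, half at 60
  h <- array(0, g$shape); h[1:5, , ] <- 60
  hv <- volume3d(g, h, role = "dose")
  mh <- dvh_metrics(hv, roi, prescription = 60, vx_thresholds = c(30))
  expect_equal(mh$mean, 30)
  expect_equal(mh$Vx[["V30"]], 50)
  ## D95 equals the sort-based 5th percentile
  set.seed(31)
  r <- array(stats::runif(1000, 10, 70), g$shape)
  rv <- volume3d(g, r, role = "dose")
  mr <- dvh_metrics(rv, roi, prescription = 60)
  expect_equal(mr$D95, unname(quantile(sort(as.vector(r)), 0.05, type = 7)),
               tolerance = 1e-12)
  expect_gte(mr$D5, mr$D95)
})

test_that("DVH curves are monotone, start at full volume and order consistently", {
  g <- unit_grid(8, 2)
  set.seed(4)
  dose <- volume3d(g, array(stats::runif(512, 0, 50), g$shape), role = "dose")
  roi <- roi_mask(g, array(stats::runif(512) < 0.5, g$shape), "r")
  curve <- compute_dvh(dose, roi, bins = 40)
  expect_equal(curve$cumulative_volume_fraction[1], 1)
  expect_true(all(diff(curve$cumulative_volume_fraction) <= 0))
  m <- dvh_metrics(dose, roi, prescription = 25)
  expect_gte(m$max, m$D5); expect_gte(m$D5, m$mean - 1e-9)
  expect_error(compute_dvh(dose, roi_mask(g, array(FALSE, g$shape), "e")),
               class = "ifp_input_error")
})

test_that("repositioning search finds exact translations and breaks ties predictably", {
  g <- grid3d(c(24, 24, 24), c(2, 2, 2), origin = rep(-23, 3))
  sph <- ifp:::sphere_mask(g, c(0, 0, 0), 10)
  a <- roi_mask(g, sph, "ctv")
  expect_equal(as.numeric(repositioning_shift(a, a)), c(0, 0, 0))
  ## daily = planning shifted by (6, 0, 0) mm with 2 mm voxels
  daily <- roi_mask(g, ifp:::sphere_mask(g, c(6, 0, 0), 10), "ctv")
  s <- repositioning_shift(a, daily, search_radius = 10, step = 2)
  expect_equal(as.numeric(s), c(6, 0, 0))
  expect_gt(attr(s, "overlap"), 0)
  ## fully disjoint beyond the radius: zero overlap flagged, finite shift returned
  far <- roi_mask(g, ifp:::sphere_mask(g, c(22, 22, 0), 3), "ctv")
  expect_warning(s2 <- repositioning_shift(a, far, search_radius = 4, step = 2),
                 "no overlap")
  expect_equal(attr(s2, "overlap"), 0L)
})

test_that("with a zero deformation all three scenarios coincide to round-off", {
  spec <- phantom_spec()
  pl <- build_phantom(spec)
  beams <- default_beams(spec$tumor$center)
  ref <- make_reference_plan(pl, beams)
  daily <- make_daily(spec, list(type = "none"))
  res <- compare_scenarios(pl, daily, daily$dvf, beams, ref$fluences)
  m <- res$metrics
  num <- as.matrix(m[, !(names(m) %in% c("scenario", "structure"))])
  o <- num[m$scenario == "original", ]
  expect_equal(num[m$scenario == "repositioning", ], o, tolerance = 1e-12)
  expect_lt(max(abs(num[m$scenario == "ifp", ] - o), na.rm = TRUE), 1e-9)
  expect_equal(as.numeric(res$shift), c(0, 0, 0))
})
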