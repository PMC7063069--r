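test_that("axis-aligned and missing rays traverse as expected", {
  g <- grid3d(c(5, 5, 5), c(1, 1, 1), origin = c(-2, -2, -2))
  ray <- list(source = c(0.2, 10, 0.3), direction = c(0, -1, 0))
  tr <- trace_ray_voxels(ray, g)
  expect_equal(nrow(tr$index), 5)
  expect_equal(tr$length, rep(1, 5))
  expect_equal(tr$index[, 1], rep(2L, 5))        # x column constant (0-based)
  miss <- list(source = c(50, 50, 50), direction = c(0, 0, 1))
  expect_equal(nrow(trace_ray_voxels(miss, g)$index), 0)
})

test_that("random oblique rays conserve chord length and match dense sampling", {
  set.seed(101)
  g <- unit_grid(8, 1)
  b <- ifp:::grid_bounds(g)
  for (i in 1:150) {
    src <- random_unit_dir() * 40
    tgt <- stats::runif(3, b$lo, b$hi)
    dir <- (tgt - src); dir <- dir / sqrt(sum(dir^2))
    tr <- trace_ray_voxels(list(source = src, direction = dir), g)
    oracle <- dense_ray_oracle(src, dir, g, n = 1e4)
    if (is.null(oracle)) {
      expect_equal(nrow(tr$index), 0)
      next
    }
    expect_equal(sum(tr$length), oracle$chord, tolerance = 1e-6)
    lin <- tr$index[, 1] + g$shape[1] * (tr$index[, 2] + g$shape[2] * tr$index[, 3])
    ## dense sampling can miss voxels whose chord is below its resolution
    big <- tr$length > 2 * oracle$step
    expect_true(all(lin[big] %in% oracle$lin))
    expect_true(all(oracle$lin %in% lin))
    common <- match(oracle$lin, lin)
    expect_lt(max(abs(tr$length[common] - oracle$length)), 3 * oracle$step)
  }
})

test_that("voxels are visited in order along the ray with positive lengths", {
  set.seed(5)
  g <- unit_grid(8, 1.3)
  for (i in 1:30) {
    src <- random_unit_dir() * 50
    dir <- -src / sqrt(sum(src^2)) + stats::rnorm(3, sd = 0.05)
    dir <- dir / sqrt(sum(dir^2))
    tr <- trace_ray_voxels(list(source = src, direction = dir), g)
    if (nrow(tr$index) < 2) next
    expect_true(all(tr$length > 0))
    ## entry parameter of each voxel must increase monotonically
    centers <- sweep(sweep(tr$index + 0.5, 2, g$spacing, "*"), 2,
                     ifp:::grid_bounds(g)$lo, "+")
    tproj <- as.vector((sweep(centers, 2, src, "-") %*% dir))
    expect_true(all(diff(tproj) > 0))
  }
})

make_plane <- function(n = 10, s = 2) plane_grid(c(n, n), c(s, s))

test_that("BEV projection of a zero field is zero with positive coverage under the ROI", {
  g <- unit_grid(8, 2)
  d <- make_dvf("zero", grid = g)
  roi <- roi_mask(g, ifp:::sphere_mask(g, c(0, 0, 0), 5), "roi")
  b <- beam_geometry(0, SAD = 1000)
  d2 <- project_dvf_to_bev(d, roi, b, make_plane())
  expect_true(all(d2$vx == 0) && all(d2$vy == 0))
  expect_gt(sum(d2$coverage > 0), 0)
})

test_that("a single-voxel ROI reproduces that voxel's projected vector", {
  g <- unit_grid(8, 2)
  v <- array(0, c(8, 8, 8, 3)); v[4, 4, 4, ] <- c(2, 1, -1)
  d <- dvf3d(g, v)
  mask <- array(FALSE, g$shape); mask[4, 4, 4] <- TRUE
  roi <- roi_mask(g, mask, "one")
  b <- beam_geometry(0, SAD = 1000)
  plane <- make_plane(12, 1)
  d2 <- project_dvf_to_bev(d, roi, b, plane)
  hit <- which(d2$coverage > 0, arr.ind = TRUE)
  expect_gt(nrow(hit), 0)
  centers <- ifp:::voxel_centers(g)
  lin <- 4 + 8 * (3 + 8 * 3)
  sb <- world_to_beam(centers[lin, ], b)
  eb <- sb + ifp:::rotate_to_beam(c(2, 1, -1), b)
  expected <- project_vector(sb, eb, 1000)
  for (r in seq_len(nrow(hit))) {
    expect_equal(c(d2$vx[hit[r, 1], hit[r, 2]], d2$vy[hit[r, 1], hit[r, 2]]),
                 expected, tolerance = 1e-9)
  }
})

test_that("per-pixel means match a brute-force per-voxel recomputation", {
  set.seed(23)
  g <- unit_grid(8, 2)
  plane <- plane_grid(c(8, 8), c(3, 3))
  for (rep in 1:2) {
    v <- array(stats::rnorm(8^3 * 3, sd = 1.5), c(8, 8, 8, 3))
    d <- dvf3d(g, v)
    mask <- array(stats::runif(8^3) < 0.35, c(8, 8, 8))
    mask[4, 4, 4] <- TRUE
    roi <- roi_mask(g, mask, "rand")
    for (gantry in c(0, 72, 144, 216, 288)) {
      b <- beam_geometry(gantry, SAD = 1000)
      got <- project_dvf_to_bev(d, roi, b, plane)
      want <- brute_force_bev(d, roi, b, plane)
      expect_equal(got$coverage, want$coverage)
      expect_lt(max(abs(got$vx - want$vx), abs(got$vy - want$vy)), 1e-9)
    }
  }
})

test_that("an in-plane translation in a depth slab magnifies by SAD/(SAD - z0)", {
  ## single voxel layer at beam depth z0 (world y for gantry 0)
  for (z0 in c(-100, 0, 100, 250)) {
    g <- grid3d(c(20, 51, 20), c(5, 10, 5), origin = c(-47.5, -250, -47.5))
    t_world <- c(1.5, 0, -2)              # zero beam-axis (world y) component
    d <- make_dvf("translation", list(shift = t_world), g)
    mask <- array(FALSE, g$shape)
    mask[, which(abs(seq(-250, 250, by = 10) - z0) < 1e-9), ] <- TRUE
    roi <- roi_mask(g, mask, "slab")
    b <- beam_geometry(0, SAD = 1000)
    plane <- plane_grid(c(10, 10), c(5, 5))
    d2 <- project_dvf_to_bev(d, roi, b, plane)
    t_b <- ifp:::rotate_to_beam(t_world, b)[1:2]
    expected <- t_b * 1000 / (1000 - z0)
    cov <- d2$coverage > 0
    expect_gt(sum(cov), 50)
    expect_lt(max(abs(d2$vx[cov] - expected[1])), 1e-6)
    expect_lt(max(abs(d2$vy[cov] - expected[2])), 1e-6)
  }
})

test_that("rotating beam and anatomy together leaves the BEV field unchanged", {
  g <- unit_grid(8, 2)
  ## anatomy: single displaced voxel ROI; rotate scene by the gantry delta
  rot_z <- function(p, ang) {
    a <- ang * pi / 180
    cbind(cos(a) * p[, 1] - sin(a) * p[, 2],
          sin(a) * p[, 1] + cos(a) * p[, 2], p[, 3])
  }
  ## use a rotationally-symmetric ROI (sphere) and a field that rotates with it
  plane <- make_plane(10, 2)
  sph <- ifp:::sphere_mask(g, c(0, 0, 0), 6)
  centers <- ifp:::voxel_centers(g)
  for (delta in c(90, 180)) {        # exact lattice rotations
    v0 <- cbind(0.04 * centers[, 1], -0.03 * centers[, 2], 0 * centers[, 3])
    d0 <- dvf3d(g, array(v0, c(g$shape, 3)))
    b0 <- beam_geometry(0, SAD = 1000)
    ref <- project_dvf_to_bev(d0, roi_mask(g, sph, "s"), b0, plane)
    v1 <- rot_z(v0[match_rotated_lin(g, delta), , drop = FALSE], delta)
    d1 <- dvf3d(g, array(v1, c(g$shape, 3)))
    b1 <- beam_geometry(delta, SAD = 1000)
    got <- project_dvf_to_bev(d1, roi_mask(g, sph, "s"), b1, plane)
    expect_equal(got$coverage, ref$coverage)
    expect_lt(max(abs(got$vx - ref$vx), abs(got$vy - ref$vy)), 1e-9)
  }
})

test_that("uncovered pixels fill by the requested mode and covered pixels never change", {
  plane <- plane_grid(c(5, 5), c(2, 2))
  vx <- matrix(0, 5, 5); vy <- matrix(0, 5, 5); cov <- matrix(0L, 5, 5)
  vx[3, 3] <- 5; cov[3, 3] <- 2L
  d <- dvf2d(plane, vx, vy, cov)
  expect_identical(fill_uncovered(d, "zero"), d)
  near <- fill_uncovered(d, "nearest")
  expect_true(all(near$vx == 5) && all(near$vy == 0))
  smooth <- fill_uncovered(d, "smooth")
  expect_equal(smooth$vx[3, 3], 5)
  expect_true(all(abs(smooth$vx) <= 5 + 1e-9))
  ## fully covered fields are unchanged by every mode
  cov2 <- matrix(1L, 5, 5)
  vx2 <- matrix(stats::rnorm(25), 5, 5)
  d2 <- dvf2d(plane, vx2, vy, cov2)
  for (m in c("zero", "nearest", "smooth"))
    expect_equal(fill_uncovered(d2, m)$vx, vx2)
  empty <- dvf2d(plane, matrix(0, 5, 5), matrix(0, 5, 5), matrix(0L, 5, 5))
  expect_error(fill_uncovered(empty, "nearest"), class = "ifp_input_error")
})

test_that("projection rejects empty ROIs and mismatched grids", {
  g <- unit_grid(6, 2)
  d <- make_dvf("zero", grid = g)
  b <- beam_geometry(0, SAD = 1000)
  expect_error(project_dvf_to_bev(d, roi_mask(g, array(FALSE, g$shape), "e"),
                                  b, make_plane()),
               class = "ifp_input_error")
  g2 <- unit_grid(5, 2)
  expect_error(project_dvf_to_bev(d, roi_mask(g2, array(TRUE, g2$shape), "m"),
                                  b, make_plane()),
               class = "ifp_input_error")
})
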