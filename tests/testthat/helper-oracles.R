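## Independent oracles used across the suite.  Each is a deliberately naive
## implementation (dense sampling, exhaustive enumeration, closed form) kept
## separate from the package's own algorithms.

## Dense-sampling ray/grid oracle: sample the ray's chord through the grid
## bounding box at `n` points and bin the samples into voxels.  Returns
## 0-based voxel indices and approximate lengths.
dense_ray_oracle <- function(source, direction, grid, n = 1e4) {
  b <- ifp:::grid_bounds(grid)
  t0 <- 0; t1 <- Inf
  for (k in 1:3) {
    if (abs(direction[k]) < 1e-300) {
      if (source[k] < b$lo[k] || source[k] > b$hi[k]) return(NULL)
    } else {
      ta <- (b$lo[k] - source[k]) / direction[k]
      tb <- (b$hi[k] - source[k]) / direction[k]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t1 <= t0) return(NULL)
  ts <- t0 + (t1 - t0) * (seq_len(n) - 0.5) / n
  p <- cbind(source[1] + ts * direction[1],
             source[2] + ts * direction[2],
             source[3] + ts * direction[3])
  idx <- floor(sweep(sweep(p, 2, b$lo, "-"), 2, grid$spacing, "/"))
  idx[idx < 0] <- 0
  for (k in 1:3) idx[idx[, k] > grid$shape[k] - 1, k] <- grid$shape[k] - 1
  lin <- idx[, 1] + grid$shape[1] * (idx[, 2] + grid$shape[2] * idx[, 3])
  counts <- table(lin)
  seg <- (t1 - t0) / n
  list(lin = as.numeric(names(counts)), length = as.numeric(counts) * seg,
       step = seg, chord = t1 - t0)
}

## Exact ray/voxel-box intersection length via the slab method (used by the
## brute-force per-voxel BEV oracle).
ray_box_overlap <- function(source, direction, lo, hi) {
  t0 <- 0; t1 <- Inf
  for (k in 1:3) {
    if (abs(direction[k]) < 1e-300) {
      if (source[k] < lo[k] || source[k] > hi[k]) return(0)
    } else {
      ta <- (lo[k] - source[k]) / direction[k]
      tb <- (hi[k] - source[k]) / direction[k]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  max(t1 - t0, 0)
}

## Brute-force recomputation of the per-pixel BEV mean: enumerate every ROI
## voxel, test the pixel ray against its box, project the crossed voxels'
## displacements and average.
brute_force_bev <- function(dvf, roi, beam, plane) {
  grid <- dvf$grid
  ax <- ifp:::plane_axes(plane)
  vmat <- matrix(dvf$vectors, ncol = 3)
  centers <- ifp:::voxel_centers(grid)
  roi_lin <- which(roi$mask)
  vx <- matrix(0, plane$shape[1], plane$shape[2])
  vy <- vx; cov <- matrix(0L, plane$shape[1], plane$shape[2])
  for (j in seq_len(plane$shape[2])) {
    for (i in seq_len(plane$shape[1])) {
      r <- pixel_ray(c(ax$x[i], ax$y[j]), beam$SAD, beam)
      crossed <- integer(0)
      for (lin in roi_lin) {
        lo <- centers[lin, ] - grid$spacing / 2
        hi <- centers[lin, ] + grid$spacing / 2
        if (ray_box_overlap(r$source, r$direction, lo, hi) > 1e-9)
          crossed <- c(crossed, lin)
      }
      cov[i, j] <- length(crossed)
      if (length(crossed) == 0L) next
      sb <- world_to_beam(centers[crossed, , drop = FALSE], beam)
      eb <- sb + ifp:::rotate_to_beam(vmat[crossed, , drop = FALSE], beam)
      pv <- project_vector(sb, eb, beam$SAD)
      vx[i, j] <- mean(pv[, 1]); vy[i, j] <- mean(pv[, 2])
    }
  }
  list(vx = vx, vy = vy, coverage = cov)
}

## Exhaustive minimal number of unit-weight interval segments summing to a
## small non-negative integer profile (step-and-shoot sweep bound oracle).
## Depth-first search with memoisation; feasible for length <= 8, h <= 4.
min_segments_oracle <- function(h) {
  memo <- new.env(parent = emptyenv())
  solve <- function(prof) {
    if (all(prof == 0)) return(0L)
    key <- paste(prof, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    i <- which(prof > 0)[1]
    best <- Inf
    for (jj in i:length(prof)) {
      if (prof[jj] == 0) break
      nxt <- prof
      nxt[i:jj] <- nxt[i:jj] - 1L
      best <- min(best, 1L + solve(nxt))
    }
    memo[[key]] <- best
    best
  }
  solve(as.integer(h))
}

## Dice similarity of two masks.
dice <- function(a, b) ifp:::dice_coefficient(a, b)

## Small uniform helper grids.
unit_grid <- function(n = 8, spacing = 1) {
  grid3d(rep(n, 3), rep(spacing, 3), origin = rep(-(n - 1) * spacing / 2, 3))
}

random_unit_dir <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

## For exact lattice rotations about z (90/180/270 deg) on a symmetric grid:
## linear index of the voxel at R(-ang) * center, for every voxel in order.
match_rotated_lin <- function(g, ang) {
  centers <- ifp:::voxel_centers(g)
  a <- -ang * pi / 180
  rot <- cbind(cos(a) * centers[, 1] - sin(a) * centers[, 2],
               sin(a) * centers[, 1] + cos(a) * centers[, 2], centers[, 3])
  idx <- round(sweep(sweep(rot, 2, g$origin, "-"), 2, g$spacing, "/"))
  1 + idx[, 1] + g$shape[1] * (idx[, 2] + g$shape[2] * idx[, 3])
}
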