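#' Planar contour set
#'
#' Per-slice closed polygons describing one structure.  Slices are indexed
#' by 0-based voxel index along the slice axis (the world z axis in v1);
#' vertices are world (x, y) coordinates in mm.  Polygons are implicitly
#' closed (the last vertex connects back to the first).
#'
#' @param structure_name label.
#' @param slices named list: names are slice indices (as characters), values
#'   are lists of n x 2 vertex matrices.
#' @param slice_axis axis label; only `"z"` is supported.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(structure_name, slices = list(), slice_axis = "z") {
  if (!identical(slice_axis, "z"))
    stop_input("contour_set: only slice_axis = 'z' is supported")
  for (sl in names(slices)) {
    for (p in slices[[sl]]) {
      p <- as.matrix(p)
      if (ncol(p) != 2L)
        stop_input("contour_set: polygons must be n x 2 vertex matrices (slice ", sl, ")")
      v <- unique(round(p, 9))
      if (nrow(v) < 3L)
        stop_input("contour_set: polygon with fewer than 3 distinct vertices on slice ", sl)
    }
  }
  structure(list(structure_name = structure_name, slices = slices,
                 slice_axis = slice_axis),
            class = "contour_set")
}

## Even-odd (crossing-number) point-in-polygon test, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  xj <- poly[n, 1]; yj <- poly[n, 2]
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    xj <- xi; yj <- yi
  }
  inside
}

#' Rasterise planar contours into a voxel mask
#'
#' Scan-line fill with the even-odd rule: a voxel belongs to the structure
#' iff its centre lies inside an odd number of the slice's polygons, so
#' holes (a polygon inside a polygon) are supported.
#'
#' @param c a [contour_set()].
#' @param grid a [grid3d()].
#' @return A [roi_mask()].
#' @export
fill_contours <- function(c, grid) {
  mask <- array(FALSE, grid$shape)
  axx <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  axy <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  px <- rep(axx, times = grid$shape[2])
  py <- rep(axy, each = grid$shape[1])
  for (sl in names(c$slices)) {
    k <- as.integer(sl)
    if (k < 0 || k >= grid$shape[3]) stop_input("fill_contours: slice ", sl, " outside grid")
    inside <- rep(FALSE, length(px))
    for (p in c$slices[[sl]]) {
      p <- as.matrix(p)
      if (nrow(p) > 1 && all(abs(p[1, ] - p[nrow(p), ]) < 1e-12))
        p <- p[-nrow(p), , drop = FALSE]       # drop explicit closing vertex
      inside <- xor(inside, points_in_polygon(px, py, p))
    }
    mask[, , k + 1L] <- mask[, , k + 1L] | matrix(inside, grid$shape[1])
  }
  roi_mask(grid, mask, name = c$structure_name)
}

#' Propagate a structure mask through a deformation field
#'
#' Backward mapping with nearest-neighbour interpolation: a daily voxel x is
#' inside the propagated structure iff the planning mask is true at the
#' planning position x + v_inv(x), where v_inv is the fixed-point inverse of
#' the planning -> daily field.  A pure translation by whole voxels is an
#' exact index shift.
#'
#' @param m planning-anatomy [roi_mask()].
#' @param dvf a [dvf3d()] (planning -> daily) on the same grid.
#' @param inverse optionally a precomputed inverse field.
#' @return The daily-anatomy [roi_mask()].
#' @export
propagate_mask <- function(m, dvf, inverse = NULL) {
  if (!same_grid(m$grid, dvf$grid))
    stop_input("propagate_mask: mask and DVF must share a grid")
  vinv <- if (is.null(inverse)) invert_dvf(dvf) else inverse
  if (max(abs(vinv$vectors)) == 0) return(m)
  pts <- voxel_centers(m$grid) + matrix(vinv$vectors, ncol = 3)
  g <- sweep(sweep(pts, 2, m$grid$origin, "-"), 2, m$grid$spacing, "/")
  idx <- round(g)
  sh <- m$grid$shape
  ok <- idx[, 1] >= 0 & idx[, 1] < sh[1] &
        idx[, 2] >= 0 & idx[, 2] < sh[2] &
        idx[, 3] >= 0 & idx[, 3] < sh[3]
  out <- rep(FALSE, prod(sh))
  lin <- 1 + idx[ok, 1] + sh[1] * (idx[ok, 2] + sh[2] * idx[ok, 3])
  out[ok] <- m$mask[lin]
  roi_mask(m$grid, array(out, sh), name = m$name)
}

#' Extract planar contours from a voxel mask
#'
#' Per-slice marching squares at iso-level 0.5 on the binary mask (the
#' slice is zero-padded so boundary structures still yield closed loops).
#' Filling the extracted contours recovers the mask up to a one-voxel
#' boundary band.
#'
#' @param m a [roi_mask()].
#' @return A [contour_set()]; empty for an empty mask.
#' @export
extract_contours <- function(m) {
  grid <- m$grid
  axx <- grid$origin[1] + (seq(-1, grid$shape[1]) ) * grid$spacing[1]
  axy <- grid$origin[2] + (seq(-1, grid$shape[2]) ) * grid$spacing[2]
  slices <- list()
  for (k in seq_len(grid$shape[3])) {
    sl <- m$mask[, , k]
    if (!any(sl)) next
    z <- matrix(0, grid$shape[1] + 2L, grid$shape[2] + 2L)
    z[2:(grid$shape[1] + 1L), 2:(grid$shape[2] + 1L)] <- sl * 1
    cl <- grDevices::contourLines(x = axx, y = axy, z = z, levels = 0.5)
    polys <- lapply(cl, function(p) {
      v <- cbind(p$x, p$y)
      if (nrow(v) > 1 && all(abs(v[1, ] - v[nrow(v), ]) < 1e-9))
        v <- v[-nrow(v), , drop = FALSE]
      v
    })
    polys <- Filter(function(v) nrow(v) >= 3, polys)
    if (length(polys)) slices[[as.character(k - 1L)]] <- polys
  }
  contour_set(m$name, slices)
}
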