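#' Regular 3-D voxel lattice
#'
#' Axis-aligned voxel grid in world coordinates.  `origin` is the world
#' coordinate of the *centre* of voxel (0,0,0); voxel indices are 0-based in
#' the geometry math (R arrays are addressed 1-based as usual).
#'
#' @param shape integer 3-vector, voxels per axis (each >= 1).
#' @param spacing numeric 3-vector, voxel size in mm (each > 0).
#' @param origin numeric 3-vector, world position (mm) of the centre of voxel
#'   (0,0,0).
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop_input("grid3d: shape must be 3 integers >= 1")
  if (!is_num(spacing, 3) || any(spacing <= 0))
    stop_input("grid3d: spacing must be 3 positive lengths (mm)")
  if (!is_num(origin, 3))
    stop_input("grid3d: origin must be a finite 3-vector (mm)")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %s voxels, spacing %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

## World-space bounding box of the voxel volume (outer voxel faces).
grid_bounds <- function(grid) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  list(lo = lo, hi = hi)
}

## World coordinates of all voxel centres as an n x 3 matrix (x fastest,
## matching R array linear order).
voxel_centers <- function(grid) {
  ax <- lapply(1:3, function(k) grid$origin[k] + (seq_len(grid$shape[k]) - 1) * grid$spacing[k])
  n <- prod(grid$shape)
  cbind(rep(ax[[1]], times = n / grid$shape[1]),
        rep(rep(ax[[2]], each = grid$shape[1]), times = grid$shape[3]),
        rep(ax[[3]], each = grid$shape[1] * grid$shape[2]))
}

#' Scalar volume on a 3-D grid
#'
#' @param grid a [grid3d()].
#' @param values numeric 3-D array matching `grid$shape` (relative electron
#'   density for anatomy volumes, Gy for dose).
#' @param role free-text label ("density", "dose", ...).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(grid, values, role = "density") {
  values <- as.array(values)
  if (!all(dim(values) == grid$shape))
    stop_input("volume3d: values shape does not match grid shape")
  if (!all(is.finite(values)))
    stop_input("volume3d: values must be finite")
  if (identical(role, "density") && any(values < 0))
    stop_input("volume3d: density volumes must be non-negative")
  structure(list(grid = grid, values = values, role = role), class = "volume3d")
}

#' Binary region-of-interest mask on a 3-D grid
#'
#' @param grid a [grid3d()].
#' @param mask logical 3-D array matching `grid$shape`.
#' @param name structure label.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(grid, mask, name = "roi") {
  mask <- as.array(mask)
  if (!all(dim(mask) == grid$shape))
    stop_input("roi_mask: mask shape does not match grid shape")
  storage.mode(mask) <- "logical"
  structure(list(grid = grid, mask = mask, name = name), class = "roi_mask")
}

mask_volume_mm3 <- function(m) sum(m$mask) * prod(m$grid$spacing)

mask_centroid <- function(m) {
  idx <- which(m$mask)
  if (length(idx) == 0L) stop_input("mask_centroid: empty mask")
  colMeans(voxel_centers(m$grid)[idx, , drop = FALSE])
}

dice_coefficient <- function(a, b) {
  2 * sum(a$mask & b$mask) / (sum(a$mask) + sum(b$mask))
}

#' Regular pixel lattice on the isocenter plane
#'
#' 2-D grid in the beam frame on which fluence maps and projected deformation
#' fields live.  `origin` is the beam-frame (x, y) of the centre of pixel
#' (0,0).
#'
#' @param shape integer 2-vector, pixels per axis.
#' @param spacing numeric 2-vector, pixel size in mm.
#' @param origin numeric 2-vector, mm.
#' @return An object of class `plane_grid`.
#' @export
plane_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop_input("plane_grid: shape must be 2 integers >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2)
  if (!is_num(spacing, 2) || any(spacing <= 0))
    stop_input("plane_grid: spacing must be positive (mm)")
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2  # centred on axis
  if (!is_num(origin, 2))
    stop_input("plane_grid: origin must be a finite 2-vector (mm)")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "plane_grid")
}

same_plane <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

## Pixel-centre coordinates along each plane axis.
plane_axes <- function(plane) {
  list(x = plane$origin[1] + (seq_len(plane$shape[1]) - 1) * plane$spacing[1],
       y = plane$origin[2] + (seq_len(plane$shape[2]) - 1) * plane$spacing[2])
}

## All pixel centres as an n x 2 matrix, x fastest (column-major order of the
## intensity matrix).
plane_centers <- function(plane) {
  ax <- plane_axes(plane)
  cbind(rep(ax$x, times = plane$shape[2]), rep(ax$y, each = plane$shape[1]))
}

## Bilinear interpolation of a matrix field at arbitrary plane points.
## Points outside the pixel-centre hull return `outside`.
bilinear_sample <- function(mat, plane, pts, outside = 0) {
  gx <- (pts[, 1] - plane$origin[1]) / plane$spacing[1]
  gy <- (pts[, 2] - plane$origin[2]) / plane$spacing[2]
  nx <- plane$shape[1]; ny <- plane$shape[2]
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  ok <- gx >= 0 & gx <= nx - 1 & gy >= 0 & gy <= ny - 1
  ## clamp so corner gathers stay in range; masked out afterwards
  i0c <- pmin(pmax(i0, 0), nx - 2 + (nx == 1)); j0c <- pmin(pmax(j0, 0), ny - 2 + (ny == 1))
  i1 <- pmin(i0c + 1, nx - 1); j1 <- pmin(j0c + 1, ny - 1)
  fxc <- ifelse(nx == 1, 0, pmin(pmax(gx - i0c, 0), 1))
  fyc <- ifelse(ny == 1, 0, pmin(pmax(gy - j0c, 0), 1))
  at <- function(i, j) mat[cbind(i + 1L, j + 1L)]
  v <- (1 - fxc) * (1 - fyc) * at(i0c, j0c) + fxc * (1 - fyc) * at(i1, j0c) +
    (1 - fxc) * fyc * at(i0c, j1) + fxc * fyc * at(i1, j1)
  v[!ok] <- outside
  v
}

## Trilinear interpolation of a 3-D array at arbitrary world points (n x 3).
## Outside the voxel-centre hull returns `outside`, or the edge-clamped
## value when `clamp = TRUE`.
trilinear_sample <- function(arr, grid, pts, outside = 0, clamp = FALSE) {
  n <- nrow(pts)
  g <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
  sh <- grid$shape
  ok <- g[, 1] >= 0 & g[, 1] <= sh[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= sh[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= sh[3] - 1
  i0 <- pmin(pmax(floor(g[, 1]), 0), max(sh[1] - 2, 0))
  j0 <- pmin(pmax(floor(g[, 2]), 0), max(sh[2] - 2, 0))
  k0 <- pmin(pmax(floor(g[, 3]), 0), max(sh[3] - 2, 0))
  fx <- if (sh[1] > 1) pmin(pmax(g[, 1] - i0, 0), 1) else rep(0, n)
  fy <- if (sh[2] > 1) pmin(pmax(g[, 2] - j0, 0), 1) else rep(0, n)
  fz <- if (sh[3] > 1) pmin(pmax(g[, 3] - k0, 0), 1) else rep(0, n)
  i1 <- pmin(i0 + 1, sh[1] - 1); j1 <- pmin(j0 + 1, sh[2] - 1); k1 <- pmin(k0 + 1, sh[3] - 1)
  lin <- function(i, j, k) arr[1L + i + sh[1] * (j + sh[2] * k)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * lin(i0, j0, k0) +
    fx * (1 - fy) * (1 - fz) * lin(i1, j0, k0) +
    (1 - fx) * fy * (1 - fz) * lin(i0, j1, k0) +
    fx * fy * (1 - fz) * lin(i1, j1, k0) +
    (1 - fx) * (1 - fy) * fz * lin(i0, j0, k1) +
    fx * (1 - fy) * fz * lin(i1, j0, k1) +
    (1 - fx) * fy * fz * lin(i0, j1, k1) +
    fx * fy * fz * lin(i1, j1, k1)
  if (!clamp) v[!ok] <- outside
  list(values = v, inside = ok)
}
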