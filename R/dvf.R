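#' 3-D deformation vector field
#'
#' Per-voxel displacement field on a regular grid.  Vectors map
#' planning-anatomy positions x to daily-anatomy positions x + v(x)
#' (start point on the planning CT, end point on the daily image).
#'
#' @param grid a [grid3d()].
#' @param vectors numeric 4-D array `c(grid$shape, 3)` of displacements, mm.
#' @return An object of class `dvf3d`.
#' @export
dvf3d <- function(grid, vectors) {
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 4L || !all(dim(vectors) == c(grid$shape, 3L)))
    stop_input("dvf3d: vectors must have shape c(grid$shape, 3)")
  if (!all(is.finite(vectors)))
    stop_input("dvf3d: displacement components must be finite")
  structure(list(grid = grid, vectors = vectors), class = "dvf3d")
}

## Evaluate an analytic displacement family at arbitrary world points.
## pts: n x 3 matrix; returns n x 3 matrix of displacements (mm).
dvf_eval <- function(kind, params, pts) {
  n <- nrow(pts)
  zero <- matrix(0, n, 3)
  taper_weight <- function(r, r_inner, r_outer) {
    w <- numeric(length(r))
    w[r <= r_inner] <- 1
    mid <- r > r_inner & r < r_outer
    w[mid] <- cos((r[mid] - r_inner) / (r_outer - r_inner) * pi / 2)^2
    w
  }
  switch(kind,
    zero = zero,
    translation = {
      t <- params$shift
      if (!is_num(t, 3)) stop_input("make_dvf: translation needs a finite 3-vector 'shift'")
      matrix(t, n, 3, byrow = TRUE)
    },
    scaling = {
      c0 <- params$center; f <- params$factor
      if (!is_num(c0, 3) || !is_num(f, 1))
        stop_input("make_dvf: scaling needs 'center' (3-vector) and 'factor'")
      (f - 1) * sweep(pts, 2, c0, "-")
    },
    gaussian_bump = {
      c0 <- params$center; a <- params$amplitude; s <- params$sigma
      if (!is_num(c0, 3) || !is_num(a, 3) || !is_num(s, 1) || s <= 0)
        stop_input("make_dvf: gaussian_bump needs 'center', 'amplitude' (3-vectors) and 'sigma' > 0")
      d2 <- rowSums(sweep(pts, 2, c0, "-")^2)
      outer(exp(-d2 / (2 * s^2)), a)
    },
    tapered_translation = {
      c0 <- params$center; t <- params$shift
      ri <- params$r_inner; ro <- params$r_outer
      if (!is_num(c0, 3) || !is_num(t, 3) || !is_num(ri, 1) || !is_num(ro, 1) || ro <= ri)
        stop_input("make_dvf: tapered_translation needs 'center', 'shift', 'r_inner' < 'r_outer'")
      r <- sqrt(rowSums(sweep(pts, 2, c0, "-")^2))
      outer(taper_weight(r, ri, ro), t)
    },
    tapered_scaling = {
      c0 <- params$center; f <- params$factor
      ri <- params$r_inner; ro <- params$r_outer
      if (!is_num(c0, 3) || !is_num(f, 1) || !is_num(ri, 1) || !is_num(ro, 1) || ro <= ri)
        stop_input("make_dvf: tapered_scaling needs 'center', 'factor', 'r_inner' < 'r_outer'")
      d <- sweep(pts, 2, c0, "-")
      r <- sqrt(rowSums(d^2))
      (f - 1) * d * taper_weight(r, ri, ro)
    },
    stop_input("make_dvf: unknown kind '", kind, "'")
  )
}

#' Construct an analytic deformation field with known ground truth
#'
#' Samples one of the analytic displacement families at the voxel centres of
#' `grid`.  These fields stand in for the output of deformable image
#' registration and give every downstream stage an exact reference.
#'
#' Families and their parameters (all lengths in mm):
#' \describe{
#'   \item{`zero`}{no displacement.}
#'   \item{`translation`}{`shift`: constant displacement.}
#'   \item{`scaling`}{`center`, `factor`: v(x) = (factor - 1)(x - center).}
#'   \item{`gaussian_bump`}{`center`, `amplitude`, `sigma`:
#'     v(x) = amplitude * exp(-|x - center|^2 / (2 sigma^2)).}
#'   \item{`tapered_translation`}{`center`, `shift`, `r_inner`, `r_outer`:
#'     rigid shift inside `r_inner`, cosine-tapered to zero by `r_outer`.}
#'   \item{`tapered_scaling`}{`center`, `factor`, `r_inner`, `r_outer`:
#'     scaling about `center` inside `r_inner`, tapered to zero by `r_outer`.}
#' }
#' The tapered families keep the far field at rest so that organs away from
#' the target are genuinely undeformed; choose
#' `(factor - 1) * r_inner / (r_outer - r_inner) < 1` (or the analogous shift
#' ratio) so the field remains invertible.
#'
#' @param kind one of the family names above.
#' @param params named list of family parameters.
#' @param grid a [grid3d()].
#' @return A [dvf3d()].
#' @export
make_dvf <- function(kind, params = list(), grid) {
  pts <- voxel_centers(grid)
  v <- dvf_eval(kind, params, pts)
  dvf3d(grid, array(v, c(grid$shape, 3L)))
}

#' Sample a deformation field at arbitrary world points
#'
#' Trilinear interpolation of the displacement vectors.  Points outside the
#' grid's voxel-centre hull return the zero vector (rays and warps routinely
#' touch the border); the number of such points is reported once per call via
#' a message when `quiet = FALSE`.
#'
#' @param dvf a [dvf3d()].
#' @param point 3-vector or n x 3 matrix of world points, mm.
#' @param quiet suppress the out-of-bounds note.
#' @param oob out-of-bounds policy: `"zero"` (default contract) or `"clamp"`
#'   (edge-value extrapolation, used by the field inversion so constant
#'   fields invert exactly).
#' @return Displacement(s), mm, same shape as `point`.
#' @export
sample_dvf <- function(dvf, point, quiet = TRUE, oob = c("zero", "clamp")) {
  oob <- match.arg(oob)
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  out <- matrix(0, nrow(pts), 3)
  inside <- NULL
  for (c_ in 1:3) {
    s <- trilinear_sample(dvf$vectors[, , , c_], dvf$grid, pts, outside = 0,
                          clamp = (oob == "clamp"))
    out[, c_] <- s$values
    inside <- s$inside
  }
  n_out <- sum(!inside)
  if (!quiet && n_out > 0)
    message("sample_dvf: ", n_out, " point(s) outside the field; zero displacement used")
  if (is.matrix(point)) out else drop(out)
}

#' Invert a deformation field by fixed-point iteration
#'
#' Iterates `v_inv(x) <- -v(x + v_inv(x))` on the voxel centres until the
#' largest update falls below `tol` or `iterations` is reached.  The inverse
#' satisfies x + v_inv(x) = y where y + v(y) = x, i.e. it maps daily
#' positions back to planning positions.  A warning reports the residual
#' `max |v(x + v_inv(x)) + v_inv(x)|` if it exceeds `tol` after the final
#' iteration (non-convergence is not a hard failure).
#'
#' @param dvf a [dvf3d()] (planning -> daily).
#' @param iterations maximum fixed-point iterations.
#' @param tol convergence tolerance on the update, mm.
#' @return A [dvf3d()] holding the inverse field (daily -> planning), with
#'   attribute `"residual"` giving the final composition residual in mm.
#' @export
invert_dvf <- function(dvf, iterations = 20, tol = 0.01) {
  pts <- voxel_centers(dvf$grid)
  vinv <- matrix(0, nrow(pts), 3)
  for (it in seq_len(iterations)) {
    new <- -sample_dvf(dvf, pts + vinv, oob = "clamp")
    delta <- max(abs(new - vinv))
    vinv <- new
    if (delta < tol) break
  }
  resid <- max(abs(sample_dvf(dvf, pts + vinv, oob = "clamp") + vinv))
  if (resid > max(tol, 0.1))
    warning(sprintf("invert_dvf: composition residual %.3g mm after %d iterations", resid, it))
  out <- dvf3d(dvf$grid, array(vinv, c(dvf$grid$shape, 3L)))
  attr(out, "residual") <- resid
  out
}

#' Warp a volume through a deformation field
#'
#' Backward mapping: the output value at a daily position x is the input
#' volume sampled (trilinearly) at the planning position x + v_inv(x), where
#' v_inv is the fixed-point inverse of the planning -> daily field.  For a
#' pure translation this is an exact shifted copy up to interpolation at
#' non-integer offsets.  Samples falling outside the input volume read 0
#' (air).
#'
#' @param vol a [volume3d()] on the same grid as `dvf`.
#' @param dvf a [dvf3d()] (planning -> daily).
#' @param inverse optionally a precomputed inverse field (skips inversion).
#' @return A [volume3d()] on the same grid.
#' @export
warp_volume <- function(vol, dvf, inverse = NULL) {
  if (!same_grid(vol$grid, dvf$grid))
    stop_input("warp_volume: volume and DVF must share a grid")
  vinv <- if (is.null(inverse)) invert_dvf(dvf) else inverse
  if (max(abs(vinv$vectors)) == 0) return(vol)  # zero field: bitwise identity
  pts <- voxel_centers(vol$grid) + matrix(vinv$vectors, ncol = 3)
  vals <- trilinear_sample(vol$values, vol$grid, pts, outside = 0)$values
  vals <- pmax(vals, 0)
  volume3d(vol$grid, array(vals, vol$grid$shape), role = vol$role)
}
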