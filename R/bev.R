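#' 2-D deformation field on the isocenter plane
#'
#' Per-pixel in-plane displacement (mm, beam frame) together with the number
#' of ROI voxels crossed by each pixel's ray (`coverage`); pixels whose rays
#' miss the ROI carry the zero vector and coverage 0.
#'
#' @param plane a [plane_grid()].
#' @param vx,vy matrices of in-plane displacement components, mm.
#' @param coverage integer matrix of crossed-ROI-voxel counts.
#' @param beam_id label of the beam the field belongs to.
#' @return An object of class `dvf2d`.
#' @export
dvf2d <- function(plane, vx, vy, coverage, beam_id = "beam") {
  if (!all(dim(vx) == plane$shape) || !all(dim(vy) == plane$shape) ||
      !all(dim(coverage) == plane$shape))
    stop_input("dvf2d: component shapes must match the plane shape")
  if (any(coverage < 0)) stop_input("dvf2d: coverage must be >= 0")
  if (any((coverage == 0) & (vx != 0 | vy != 0)))
    stop_input("dvf2d: uncovered pixels must carry the zero vector")
  structure(list(plane = plane, vx = vx, vy = vy,
                 coverage = matrix(as.integer(coverage), plane$shape[1]),
                 beam_id = beam_id),
            class = "dvf2d")
}

#' Voxels crossed by a ray
#'
#' Incremental (Amanatides-Woo) traversal of the grid along a ray, returning
#' every voxel intersected with positive chord length, in order along the
#' ray.  Grazing contacts shorter than 1e-9 mm are treated as not crossed.
#'
#' @param ray a [pixel_ray()] (or any list with world `source` and unit
#'   `direction`).
#' @param grid a [grid3d()].
#' @return A list with `index` (n x 3 matrix of 0-based voxel indices) and
#'   `length` (chord length per voxel, mm).  A ray missing the volume
#'   returns zero rows.
#' @export
trace_ray_voxels <- function(ray, grid) {
  d <- ray$direction
  nd <- sqrt(sum(d^2))
  if (abs(nd - 1) > 1e-9) stop_input("trace_ray_voxels: direction must be a unit vector")
  cpp_trace_ray(as.numeric(ray$source), as.numeric(d),
                grid$shape, grid$spacing, grid$origin)
}

## Rotation of world vectors into the beam frame (directions only).
rotate_to_beam <- function(v, beam) {
  R <- beam_axes(beam)
  if (is.matrix(v)) v %*% R else drop(crossprod(R, v))
}

#' Project a 3-D deformation field into a beam's-eye-view 2-D field
#'
#' For every pixel of the isocenter-plane grid, casts the pixel's divergent
#' ray from the source, collects the ROI voxels the ray crosses, projects
#' each crossed voxel's 3-D displacement onto the isocenter plane (both
#' endpoints projected through the source, Eqs. of the divergent geometry)
#' and stores the unweighted mean of the projected vectors; `coverage`
#' records the number of contributing voxels, and uncovered pixels get the
#' zero vector.
#'
#' @param dvf a [dvf3d()] on the same grid as `roi`.
#' @param roi a [roi_mask()]; must contain at least one voxel.
#' @param beam a [beam_geometry()].
#' @param plane a [plane_grid()] for the output field.
#' @param length_weighted if `TRUE`, weight each voxel's projected vector by
#'   the ray's chord length through it instead of the plain mean
#'   (sensitivity variant; the plain mean is the reference behaviour).
#' @param supersample integer s >= 1; cast s x s sub-rays per pixel and pool
#'   their crossed voxels.
#' @return A [dvf2d()].
#' @export
project_dvf_to_bev <- function(dvf, roi, beam, plane,
                               length_weighted = FALSE, supersample = 1L) {
  if (!same_grid(dvf$grid, roi$grid))
    stop_input("project_dvf_to_bev: DVF and ROI must share a grid")
  if (!any(roi$mask)) stop_input("project_dvf_to_bev: ROI is empty")
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop_input("project_dvf_to_bev: supersample must be >= 1")
  grid <- dvf$grid
  sh <- grid$shape
  vmat <- matrix(dvf$vectors, ncol = 3)          # voxel displacements, world
  centers_cache <- voxel_centers(grid)
  ax <- plane_axes(plane)
  nx <- plane$shape[1]; ny <- plane$shape[2]
  vx <- matrix(0, nx, ny); vy <- matrix(0, nx, ny)
  cov <- matrix(0L, nx, ny)
  ## sub-pixel offsets (centred) for optional supersampling
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      lins <- integer(0); lens <- numeric(0)
      for (oy in offs) {
        for (ox in offs) {
          r <- pixel_ray(c(ax$x[i] + ox * plane$spacing[1],
                           ax$y[j] + oy * plane$spacing[2]),
                         beam$SAD, beam, pixel_index = c(i - 1L, j - 1L))
          tr <- cpp_trace_ray(r$source, r$direction, sh, grid$spacing, grid$origin)
          if (nrow(tr$index) == 0L) next
          lin <- 1L + tr$index[, 1] + sh[1] * (tr$index[, 2] + sh[2] * tr$index[, 3])
          keep <- roi$mask[lin]
          lins <- c(lins, lin[keep]); lens <- c(lens, tr$length[keep])
        }
      }
      n <- length(lins)
      cov[i, j] <- n
      if (n == 0L) next
      start_w <- centers_cache[lins, , drop = FALSE]
      vec_w <- vmat[lins, , drop = FALSE]
      start_b <- world_to_beam(start_w, beam)
      end_b <- start_b + rotate_to_beam(vec_w, beam)
      pv <- project_vector(start_b, end_b, beam$SAD)
      if (length_weighted) {
        w <- lens / sum(lens)
        vx[i, j] <- sum(pv[, 1] * w); vy[i, j] <- sum(pv[, 2] * w)
      } else {
        vx[i, j] <- mean(pv[, 1]); vy[i, j] <- mean(pv[, 2])
      }
    }
  }
  dvf2d(plane, vx, vy, cov, beam_id = beam$beam_id)
}

#' Fill pixels whose rays missed the ROI
#'
#' @param d a [dvf2d()].
#' @param mode `"zero"` (leave uncovered pixels at the zero vector, the
#'   default: fluence outside the ROI shadow stays as planned), `"nearest"`
#'   (copy the nearest covered pixel's vector) or `"smooth"` (Laplace
#'   interpolation with covered pixels as boundary values).  Covered pixels
#'   are unchanged in every mode.
#' @return A [dvf2d()] with the same coverage map.
#' @export
fill_uncovered <- function(d, mode = c("zero", "nearest", "smooth")) {
  mode <- match.arg(mode)
  if (mode == "zero" || all(d$coverage > 0)) return(d)
  if (!any(d$coverage > 0)) stop_input("fill_uncovered: no covered pixel")
  covered <- d$coverage > 0
  vx <- d$vx; vy <- d$vy
  if (mode == "nearest") {
    pc <- plane_centers(d$plane)
    ci <- which(covered); ui <- which(!covered)
    pcov <- pc[ci, , drop = FALSE]
    for (u in ui) {
      dd <- (pcov[, 1] - pc[u, 1])^2 + (pcov[, 2] - pc[u, 2])^2
      k <- ci[which.min(dd)]
      vx[u] <- d$vx[k]; vy[u] <- d$vy[k]
    }
  } else {  # smooth: Jacobi relaxation of the Laplace equation
    for (comp in 1:2) {
      f <- if (comp == 1) d$vx else d$vy
      g <- f; g[!covered] <- 0
      nx <- d$plane$shape[1]; ny <- d$plane$shape[2]
      for (it in seq_len(400)) {
        gp <- rbind(g[1, , drop = FALSE], g[-nx, , drop = FALSE])
        gn <- rbind(g[-1, , drop = FALSE], g[nx, , drop = FALSE])
        gl <- cbind(g[, 1, drop = FALSE], g[, -ny, drop = FALSE])
        gr <- cbind(g[, -1, drop = FALSE], g[, ny, drop = FALSE])
        new <- (gp + gn + gl + gr) / 4
        new[covered] <- f[covered]
        if (max(abs(new - g)) < 1e-8) { g <- new; break }
        g <- new
      }
      if (comp == 1) vx <- g else vy <- g
    }
  }
  out <- d
  out$vx <- vx; out$vy <- vy
  out
}
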