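#' 2-D fluence map on the isocenter plane
#'
#' Relative ray-intensity distribution I(x, y) of one beam, defined on a
#' [plane_grid()] in the beam frame.
#'
#' @param plane a [plane_grid()].
#' @param intensity non-negative finite matrix matching `plane$shape`.
#' @param beam_id label.
#' @return An object of class `fluence_grid`.
#' @export
fluence_grid <- function(plane, intensity, beam_id = "beam") {
  intensity <- as.matrix(intensity)
  if (!all(dim(intensity) == plane$shape))
    stop_input("fluence_grid: intensity shape must match the plane shape")
  if (!all(is.finite(intensity)) || any(intensity < 0))
    stop_input("fluence_grid: intensity must be finite and >= 0")
  structure(list(plane = plane, intensity = intensity, beam_id = beam_id),
            class = "fluence_grid")
}

#' Deform a fluence map along a 2-D deformation field
#'
#' `push` (default) transports intensity *values* with the deformation: each
#' pixel's value is carried to (pixel centre + vector) and splatted with
#' bilinear weights; accumulated values are normalised by the accumulated
#' weights, so a uniform region keeps its intensity level under expansion or
#' contraction (the deformed distribution I'(x', y') takes the value of
#' I(x, y) at the displaced coordinate).  `pull` samples the input at
#' (pixel centre - vector) by bilinear interpolation.  Target pixels that
#' receive no mass under `push` (possible under strongly expansive fields)
#' are left at zero; intensity transported beyond the grid is dropped, with
#' the dropped fraction recorded in attribute `"dropped_fraction"`.
#'
#' @param f a [fluence_grid()].
#' @param d a [dvf2d()] on the same plane.
#' @param mode `"push"` or `"pull"`.
#' @param conserve_total rescale the output so its intensity sum equals the
#'   input sum exactly (MU renormalisation; default off).
#' @return A [fluence_grid()].
#' @export
warp_fluence <- function(f, d, mode = c("push", "pull"), conserve_total = FALSE) {
  mode <- match.arg(mode)
  if (!same_plane(f$plane, d$plane))
    stop_input("warp_fluence: fluence and deformation field planes differ")
  if (!all(is.finite(d$vx)) || !all(is.finite(d$vy)))
    stop_input("warp_fluence: non-finite deformation vectors")
  plane <- f$plane
  nx <- plane$shape[1]; ny <- plane$shape[2]
  if (all(d$vx == 0) && all(d$vy == 0)) {
    out <- f$intensity                       # zero field: exact identity
  } else if (mode == "pull") {
    pc <- plane_centers(plane)
    src <- cbind(pc[, 1] - as.vector(d$vx), pc[, 2] - as.vector(d$vy))
    out <- matrix(bilinear_sample(f$intensity, plane, src, outside = 0), nx, ny)
  } else {
    pc <- plane_centers(plane)
    gx <- (pc[, 1] + as.vector(d$vx) - plane$origin[1]) / plane$spacing[1]
    gy <- (pc[, 2] + as.vector(d$vy) - plane$origin[2]) / plane$spacing[2]
    val <- as.vector(f$intensity)
    i0 <- floor(gx); j0 <- floor(gy)
    fx <- gx - i0; fy <- gy - j0
    num <- numeric(nx * ny); den <- numeric(nx * ny)
    for (ci in 0:1) {
      for (cj in 0:1) {
        ii <- i0 + ci; jj <- j0 + cj
        w <- (if (ci == 0) 1 - fx else fx) * (if (cj == 0) 1 - fy else fy)
        ok <- ii >= 0 & ii < nx & jj >= 0 & jj < ny & w > 0
        if (!any(ok)) next
        lin <- 1L + ii[ok] + nx * jj[ok]
        acc_n <- rowsum(w[ok] * val[ok], lin)
        acc_d <- rowsum(w[ok], lin)
        at <- as.integer(rownames(acc_n))
        num[at] <- num[at] + acc_n[, 1]
        den[at] <- den[at] + acc_d[, 1]
      }
    }
    out <- matrix(ifelse(den > 1e-12, num / den, 0), nx, ny)
  }
  if (conserve_total) {
    s <- sum(out)
    if (s > 0) out <- out * (sum(f$intensity) / s)
  }
  out <- pmax(out, 0)                        # guard; interpolation is monotone
  res <- fluence_grid(plane, out, beam_id = f$beam_id)
  attr(res, "dropped_fraction") <-
    if (sum(f$intensity) > 0) max(0, 1 - sum(out) / sum(f$intensity)) else 0
  res
}

#' Summary statistics of a fluence map
#'
#' @param f a [fluence_grid()].
#' @param open_threshold fraction of the maximum intensity above which a
#'   pixel counts as open (default 1 percent).
#' @return A list with `total` (intensity integral, intensity x mm^2), `max`,
#'   `centroid` (intensity-weighted mean position, mm; `NA` and a note when
#'   the map is all zero) and `open_area` (mm^2).
#' @export
fluence_stats <- function(f, open_threshold = 0.01) {
  px_area <- prod(f$plane$spacing)
  tot <- sum(f$intensity)
  if (tot == 0) {
    return(list(total = 0, max = 0, centroid = c(NA_real_, NA_real_),
                open_area = 0, note = "all-zero fluence: centroid undefined"))
  }
  pc <- plane_centers(f$plane)
  w <- as.vector(f$intensity) / tot
  centroid <- c(sum(pc[, 1] * w), sum(pc[, 2] * w))
  open_area <- sum(f$intensity > open_threshold * max(f$intensity)) * px_area
  list(total = tot * px_area, max = max(f$intensity),
       centroid = centroid, open_area = open_area)
}
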