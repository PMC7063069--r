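#' Beam geometry in IEC-61217 gantry coordinates
#'
#' Describes one coplanar treatment beam.  The beam frame has its origin at
#' the isocenter with +Z pointing from the isocenter toward the source, so
#' the source sits at beam-frame (0, 0, SAD) and the beam travels along -Z.
#' At gantry 0 deg the beam points downward: +Y world is toward the source,
#' and the gantry rotates about the world Z axis (patient longitudinal axis).
#'
#' @param gantry_angle gantry angle in degrees, in \[0, 360).
#' @param SAD source-axis distance in mm (> 0).
#' @param isocenter world coordinates of the isocenter, mm.
#' @param collimator_angle collimator angle in degrees; only 0 is supported.
#' @param beam_id label.
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(gantry_angle, SAD = 1000, isocenter = c(0, 0, 0),
                          collimator_angle = 0, beam_id = "beam") {
  if (!is_num(gantry_angle, 1) || gantry_angle < 0 || gantry_angle >= 360)
    stop_input("beam_geometry: gantry_angle must be in [0, 360) degrees")
  if (!is_num(SAD, 1) || SAD <= 0)
    stop_input("beam_geometry: SAD must be > 0 mm")
  if (!is_num(isocenter, 3))
    stop_input("beam_geometry: isocenter must be a finite 3-vector (mm)")
  if (!is_num(collimator_angle, 1) || collimator_angle != 0)
    stop_input("beam_geometry: only collimator_angle = 0 is supported")
  structure(list(beam_id = as.character(beam_id),
                 gantry_angle = as.numeric(gantry_angle),
                 SAD = as.numeric(SAD),
                 isocenter = as.numeric(isocenter),
                 collimator_angle = 0),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("beam '%s': gantry %g deg, SAD %g mm, isocenter (%s) mm\n",
              x$beam_id, x$gantry_angle, x$SAD,
              paste(format(x$isocenter), collapse = ", ")))
  invisible(x)
}

## 3x3 rotation matrix whose columns are the beam-frame axes expressed in
## world coordinates.  e_z points from isocenter toward the source.
beam_axes <- function(beam) {
  g <- beam$gantry_angle * pi / 180
  ez <- c(sin(g), cos(g), 0)
  ey <- c(0, 0, 1)                      # leaf rows stack along the patient axis
  ex <- c(-cos(g), sin(g), 0)           # ey x ez, right-handed
  unname(cbind(ex, ey, ez))
}

#' Transform world points into a beam's gantry frame
#'
#' The beam frame has origin at the isocenter and +Z toward the source.
#'
#' @param point numeric 3-vector or n x 3 matrix of world points, mm.
#' @param beam a [beam_geometry()].
#' @return Same shape as `point`, in beam-frame mm.
#' @export
world_to_beam <- function(point, beam) {
  R <- beam_axes(beam)
  if (is.matrix(point)) {
    sweep(point, 2, beam$isocenter, "-") %*% R
  } else {
    drop(crossprod(R, point - beam$isocenter))
  }
}

#' Inverse of [world_to_beam()]
#'
#' @inheritParams world_to_beam
#' @export
beam_to_world <- function(point, beam) {
  R <- beam_axes(beam)
  if (is.matrix(point)) {
    sweep(point %*% t(R), 2, beam$isocenter, "+")
  } else {
    drop(R %*% point) + beam$isocenter
  }
}

#' Divergent projection of a beam-frame point onto the isocenter plane
#'
#' Projects along the ray from the source (at beam-frame (0,0,SAD)) through
#' the point onto the plane z = 0: `x' = x SAD / (SAD - z)`, likewise for y,
#' and `z' = 0`.  Points at or behind the source (z >= SAD) are a geometry
#' error.
#'
#' @param p beam-frame 3-vector or n x 3 matrix, mm.
#' @param SAD source-axis distance, mm.
#' @return Projected point(s) on the plane, same shape as `p`.
#' @export
project_point <- function(p, SAD) {
  m <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  if (any(m[, 3] >= SAD))
    stop_geometry("project_point: point at or behind the source (z = ",
                  format(max(m[, 3])), " mm >= SAD = ", format(SAD), " mm)")
  s <- SAD / (SAD - m[, 3])
  out <- cbind(m[, 1] * s, m[, 2] * s, 0)
  if (is.matrix(p)) out else drop(out)
}

#' Projection of a 3-D deformation vector onto the isocenter plane
#'
#' Both endpoints of the vector are projected with [project_point()] and the
#' in-plane difference (end' - start') is returned: the projected deformation
#' vector a'.
#'
#' @param start,end beam-frame 3-vectors or n x 3 matrices, mm.
#' @param SAD source-axis distance, mm.
#' @return 2-vector (or n x 2 matrix) in mm on the isocenter plane.
#' @export
project_vector <- function(start, end, SAD) {
  ps <- project_point(start, SAD)
  pe <- project_point(end, SAD)
  if (is.matrix(ps)) pe[, 1:2, drop = FALSE] - ps[, 1:2, drop = FALSE]
  else (pe - ps)[1:2]
}

#' Ray through a fluence pixel
#'
#' Builds the ray from the beam source through a point on the isocenter
#' plane, expressed in world coordinates.
#'
#' @param pixel_center beam-frame (x, y) of the pixel centre on the isocenter
#'   plane, mm.
#' @param SAD source-axis distance, mm.
#' @param beam a [beam_geometry()].
#' @param pixel_index optional integer 2-vector recording which fluence pixel
#'   the ray belongs to.
#' @return An object of class `ray` with fields `source` (world mm),
#'   `direction` (unit world vector) and `pixel_index`.
#' @export
pixel_ray <- function(pixel_center, SAD, beam, pixel_index = c(NA_integer_, NA_integer_)) {
  if (!is_num(pixel_center, 2))
    stop_input("pixel_ray: pixel_center must be a finite 2-vector (mm)")
  src_b <- c(0, 0, SAD)
  tgt_b <- c(pixel_center, 0)
  src_w <- beam_to_world(src_b, beam)
  tgt_w <- beam_to_world(tgt_b, beam)
  d <- tgt_w - src_w
  d <- d / sqrt(sum(d^2))
  structure(list(source = src_w, direction = d,
                 pixel_index = as.integer(pixel_index)),
            class = "ray")
}
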