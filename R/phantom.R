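#' Synthetic thorax phantom specification
#'
#' Analytic scene description from which planning and daily anatomies are
#' rasterised: an elliptical body, two low-density lungs, a spherical gross
#' tumour volume inside the right lung and a spinal-cord cylinder.  The CTV
#' is the tumour with a 5 mm radial margin and the PTV adds a further 5 mm
#' in all directions; because the shapes are spheres, both margins are
#' rasterised analytically (a sphere grown by its margin), keeping the masks
#' exact and consistent with the analytic ground-truth deformations.
#'
#' @param grid a [grid3d()]; default 64^3 voxels of 2.5 mm centred on the
#'   origin.
#' @param body list(center, radii) of the body ellipsoid, mm.
#' @param lungs list of two list(center, radii) ellipsoids, mm.
#' @param tumor list(center, radius) of the gross tumour volume, mm.
#' @param cord list(center (x, y), radius) of the cord cylinder (axis along
#'   z, full grid extent), mm.
#' @param densities named relative electron densities (> 0) for body, lung,
#'   tumor, cord.
#' @param margins named mm margins: `ctv` (tumour to CTV) and `ptv` (CTV to
#'   PTV), both 5 mm.
#' @param noise_sd standard deviation of optional additive Gaussian density
#'   noise (0 disables it).
#' @param seed integer seed used for the density noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = grid3d(c(64, 64, 64), c(2.5, 2.5, 2.5),
                                       origin = c(-78.75, -78.75, -78.75)),
                         body = list(center = c(0, 0, 0), radii = c(75, 65, 76)),
                         lungs = list(list(center = c(-38, 5, 0), radii = c(28, 40, 60)),
                                      list(center = c(38, 5, 0), radii = c(28, 40, 60))),
                         tumor = list(center = c(25, 0, 0), radius = 20),
                         cord = list(center = c(0, -55), radius = 5),
                         densities = c(body = 1.0, lung = 0.25, tumor = 1.0, cord = 1.05),
                         margins = c(ctv = 5, ptv = 5),
                         noise_sd = 0, seed = 1L) {
  if (any(densities <= 0)) stop_input("phantom_spec: densities must be > 0")
  b <- grid_bounds(grid)
  ptv_r <- tumor$radius + sum(margins)
  if (any(tumor$center - ptv_r < b$lo) || any(tumor$center + ptv_r > b$hi))
    stop_input("phantom_spec: target (PTV) leaves the grid")
  if (sum(((tumor$center - body$center) / body$radii)^2) >= 1)
    stop_input("phantom_spec: tumor centre outside the body")
  structure(list(grid = grid, body = body, lungs = lungs, tumor = tumor,
                 cord = cord, densities = densities, margins = margins,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipsoid_mask <- function(grid, center, radii, pts = voxel_centers(grid)) {
  d <- sweep(pts, 2, center, "-")
  inside <- (d[, 1] / radii[1])^2 + (d[, 2] / radii[2])^2 + (d[, 3] / radii[3])^2 <= 1
  array(inside, grid$shape)
}

sphere_mask <- function(grid, center, radius, pts = voxel_centers(grid)) {
  ellipsoid_mask(grid, center, rep(radius, 3), pts)
}

cylinder_mask_z <- function(grid, center_xy, radius, pts = voxel_centers(grid)) {
  inside <- (pts[, 1] - center_xy[1])^2 + (pts[, 2] - center_xy[2])^2 <= radius^2
  array(inside, grid$shape)
}

## Rasterise the scene.  `pts` are the (possibly pre-image-transformed)
## world positions tested against the analytic shapes: passing the
## analytically inverted voxel centres rasterises the *deformed* scene
## exactly, so daily masks and the ground-truth field agree by construction.
rasterize_scene <- function(spec, pts = voxel_centers(spec$grid)) {
  grid <- spec$grid
  body <- ellipsoid_mask(grid, spec$body$center, spec$body$radii, pts)
  lung_l <- ellipsoid_mask(grid, spec$lungs[[1]]$center, spec$lungs[[1]]$radii, pts) & body
  lung_r <- ellipsoid_mask(grid, spec$lungs[[2]]$center, spec$lungs[[2]]$radii, pts) & body
  gtv <- sphere_mask(grid, spec$tumor$center, spec$tumor$radius, pts)
  ctv <- sphere_mask(grid, spec$tumor$center, spec$tumor$radius + spec$margins[["ctv"]], pts)
  ptv <- sphere_mask(grid, spec$tumor$center, spec$tumor$radius + sum(spec$margins), pts)
  cord <- cylinder_mask_z(grid, spec$cord$center, spec$cord$radius, pts) & body
  if (any(gtv & cord))
    warning("phantom: tumor and cord overlap")
  dens <- array(0, grid$shape)
  dens[body] <- spec$densities[["body"]]
  dens[lung_l | lung_r] <- spec$densities[["lung"]]
  dens[gtv] <- spec$densities[["tumor"]]
  dens[cord] <- spec$densities[["cord"]]
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    dens <- pmax(dens + array(stats::rnorm(length(dens), 0, spec$noise_sd),
                              grid$shape), 0)
  }
  masks <- list(
    body = roi_mask(grid, body, "body"),
    lung_l = roi_mask(grid, lung_l, "lung_l"),
    lung_r = roi_mask(grid, lung_r, "lung_r"),
    lungs = roi_mask(grid, lung_l | lung_r, "lungs"),
    cord = roi_mask(grid, cord, "cord"),
    gtv = roi_mask(grid, gtv, "gtv"),
    ctv = roi_mask(grid, ctv, "ctv"),
    ptv = roi_mask(grid, ptv, "ptv"))
  list(density = volume3d(grid, dens, role = "density"), masks = masks)
}

#' Rasterise the planning anatomy
#'
#' @param spec a [phantom_spec()].
#' @return A list with `density` (a [volume3d()]) and `masks` (named list of
#'   [roi_mask()]s: body, lung_l, lung_r, lungs, cord, gtv, ctv, ptv).
#'   Deterministic given the spec (the noise, if enabled, is seeded).
#' @export
build_phantom <- function(spec) {
  rasterize_scene(spec)
}

## Analytic inverse of x -> x + v(x) for the displacement families, by
## fixed-point iteration on the *analytic* field (no grid sampling):
## returns the pre-image positions phi^{-1}(pts).
invert_points_analytic <- function(kind, params, pts, iterations = 150, tol = 1e-6) {
  vinv <- matrix(0, nrow(pts), 3)
  for (it in seq_len(iterations)) {
    new <- -dvf_eval(kind, params, pts + vinv)
    if (max(abs(new - vinv)) < tol) { vinv <- new; break }
    vinv <- new
  }
  pts + vinv
}

#' Dilate a mask by a Euclidean margin
#'
#' A voxel belongs to the dilated mask iff its centre lies within `margin`
#' mm of the centre of a mask voxel (Euclidean distance on the lattice;
#' margin 0 is the identity).
#'
#' @param m a [roi_mask()].
#' @param margin margin in mm (>= 0).
#' @return A [roi_mask()].
#' @export
expand_margin <- function(m, margin) {
  if (margin < 0) stop_input("expand_margin: margin must be >= 0")
  if (margin == 0) return(m)
  sp <- m$grid$spacing
  kmax <- floor(margin / sp)
  offs <- as.matrix(expand.grid(-kmax[1]:kmax[1], -kmax[2]:kmax[2], -kmax[3]:kmax[3]))
  offs <- offs[sqrt(rowSums(sweep(offs, 2, sp, "*")^2)) <= margin + 1e-9, , drop = FALSE]
  sh <- m$grid$shape
  out <- array(FALSE, sh)
  ijk <- which(m$mask, arr.ind = TRUE) - 1L
  for (r in seq_len(nrow(offs))) {
    i <- ijk[, 1] + offs[r, 1]; j <- ijk[, 2] + offs[r, 2]; k <- ijk[, 3] + offs[r, 3]
    ok <- i >= 0 & i < sh[1] & j >= 0 & j < sh[2] & k >= 0 & k < sh[3]
    out[1 + i[ok] + sh[1] * (j[ok] + sh[2] * k[ok])] <- TRUE
  }
  roi_mask(m$grid, out, name = m$name)
}

#' Generate a daily anatomy with analytic ground-truth deformation
#'
#' The daily anatomy is the exact analytic image of the planning scene
#' under the deformation: each voxel centre is pulled back through the
#' analytically inverted map and tested against the planning shapes, so the
#' daily masks (including slightly displaced organs at risk in the taper
#' zone) and the returned ground-truth field are consistent by construction
#' rather than produced by voxel warping.  The supported deformations act
#' rigidly (or as a pure scaling) on the target inside `r_inner` and taper
#' smoothly to zero by `r_outer`, so distant anatomy is at rest; the daily
#' CTV/PTV are the deformed images of the planning CTV/PTV.
#'
#' @param spec a [phantom_spec()].
#' @param deformation list with `type` in `"none"`, `"shift"` (field
#'   `shift`, 3-vector mm) or `"expand"` (field `factor` > 0), plus taper
#'   radii `r_inner` (default 40) and `r_outer` (default 65) about the
#'   tumour centre.
#' @return A list with `density`, `masks` (daily), and `dvf` (the
#'   ground-truth planning-to-daily [dvf3d()]).
#' @export
make_daily <- function(spec, deformation = list(type = "none")) {
  ri <- if (is.null(deformation$r_inner)) 40 else deformation$r_inner
  ro <- if (is.null(deformation$r_outer)) 65 else deformation$r_outer
  c0 <- spec$tumor$center
  type <- deformation$type
  if (type == "none") {
    scene <- build_phantom(spec)
    dvf <- make_dvf("zero", grid = spec$grid)
    return(c(scene, list(dvf = dvf)))
  }
  ptv_r0 <- spec$tumor$radius + sum(spec$margins)
  if (type == "shift") {
    t <- deformation$shift
    if (!is_num(t, 3)) stop_input("make_daily: shift deformation needs a 3-vector 'shift'")
    kind <- "tapered_translation"
    params <- list(center = c0, shift = t, r_inner = ri, r_outer = ro)
    new_center <- c0 + t
    ptv_r <- ptv_r0
    reach <- sqrt(sum(t^2)) + ptv_r0
  } else if (type == "expand") {
    f <- deformation$factor
    if (!is_num(f, 1) || f <= 0) stop_input("make_daily: expand deformation needs 'factor' > 0")
    kind <- "tapered_scaling"
    params <- list(center = c0, factor = f, r_inner = ri, r_outer = ro)
    new_center <- c0
    ptv_r <- f * ptv_r0
    reach <- ptv_r
  } else stop_input("make_daily: unknown deformation type '", type, "'")
  if (reach > ri)
    stop_input("make_daily: deformed target exceeds the rigid core radius r_inner")
  b <- grid_bounds(spec$grid)
  if (any(new_center - ptv_r < b$lo) || any(new_center + ptv_r > b$hi))
    stop_input("make_daily: deformed structure leaves the grid")
  pts <- invert_points_analytic(kind, params, voxel_centers(spec$grid))
  scene <- rasterize_scene(spec, pts)
  dvf <- make_dvf(kind, params, spec$grid)
  c(scene, list(dvf = dvf))
}

#' Default coplanar beam arrangement
#'
#' Evenly spaced coplanar beams (gantry 0, 360/n, ... degrees) with a common
#' isocenter.
#'
#' @param isocenter world isocenter, mm (typically the planning CTV centre).
#' @param n number of beams.
#' @param SAD source-axis distance, mm.
#' @return List of [beam_geometry()].
#' @export
default_beams <- function(isocenter, n = 5, SAD = 1000) {
  lapply(seq_len(n) - 1L, function(i)
    beam_geometry(gantry_angle = i * 360 / n, SAD = SAD, isocenter = isocenter,
                  beam_id = sprintf("B%d", i + 1L)))
}

#' Default fluence-plane grid
#'
#' @param shape pixels per axis.
#' @param spacing pixel size, mm.
#' @return A [plane_grid()] centred on the beam axis.
#' @export
default_plane <- function(shape = c(48, 48), spacing = c(2.5, 2.5)) {
  plane_grid(shape, spacing)
}

#' Conformal reference plan calibrated to the prescription
#'
#' For each beam, opens (with uniform intensity) every fluence pixel onto
#' which at least one PTV voxel centre projects through the divergent
#' geometry, then scales all beams jointly so that the PTV D95 on the
#' planning anatomy equals the prescription.
#'
#' @param phantom output of [build_phantom()].
#' @param beams list of [beam_geometry()].
#' @param prescription prescription dose, Gy.
#' @param plane a [plane_grid()]; default [default_plane()].
#' @param mu_per_mm attenuation coefficient passed to the dose engine.
#' @return A list with `fluences` (calibrated [fluence_grid()]s), `scale`
#'   (the calibration factor applied to unit fluence), `dose` (the
#'   calibrated planning dose) and `plane`.
#' @export
make_reference_plan <- function(phantom, beams, prescription = 60,
                                plane = default_plane(), mu_per_mm = 5e-4) {
  if (length(beams) < 1L) stop_input("make_reference_plan: need at least one beam")
  ptv <- phantom$masks$ptv
  if (!any(ptv$mask)) stop_input("make_reference_plan: PTV is empty")
  centers <- voxel_centers(ptv$grid)[which(ptv$mask), , drop = FALSE]
  fluences <- lapply(beams, function(b) {
    pb <- world_to_beam(centers, b)
    pr <- project_point(pb, b$SAD)
    gx <- round((pr[, 1] - plane$origin[1]) / plane$spacing[1])
    gy <- round((pr[, 2] - plane$origin[2]) / plane$spacing[2])
    ok <- gx >= 0 & gx < plane$shape[1] & gy >= 0 & gy < plane$shape[2]
    if (!any(ok)) stop_input("make_reference_plan: PTV shadow empty for beam ", b$beam_id)
    open <- matrix(FALSE, plane$shape[1], plane$shape[2])
    open[cbind(gx[ok] + 1L, gy[ok] + 1L)] <- TRUE
    fluence_grid(plane, open * 1, beam_id = b$beam_id)
  })
  plans <- Map(function(b, f) list(beam = b, fluence = f), beams, fluences)
  dose_unit <- compute_dose(plans, phantom$density, list(mu_per_mm = mu_per_mm))
  d95 <- dvh_metrics(dose_unit, ptv, prescription)$D95
  if (d95 <= 0) stop_input("make_reference_plan: zero PTV D95; check geometry")
  scale <- prescription / d95
  fluences <- lapply(fluences, function(f)
    fluence_grid(f$plane, f$intensity * scale, beam_id = f$beam_id))
  dose <- volume3d(dose_unit$grid, dose_unit$values * scale, role = "dose")
  list(fluences = fluences, scale = scale, dose = dose, plane = plane)
}
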