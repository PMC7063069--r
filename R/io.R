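## File formats: volumes, masks and 3-D deformation fields are NIfTI
## (.nii.gz) with a JSON geometry sidecar (<file>.json) carrying the grid
## origin and role, since the package's grids are axis-aligned with the
## origin defined at the centre of voxel (0,0,0).  Fluence maps and 2-D
## deformation fields are CSV matrices with a JSON sidecar; beams, aperture
## plans and contour sets are JSON documents.

sidecar_path <- function(path) paste0(path, ".json")

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_json_file <- function(path) {
  if (!file.exists(path)) stop_input("missing file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a scalar volume as NIfTI
#'
#' @param vol a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`); a JSON sidecar
#'   `<path>.json` records the grid origin (mm) and role.
#' @return `read_volume` returns a [volume3d()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values, pixdim = vol$grid$spacing)
  RNifti::writeNifti(img, path)
  write_json_file(list(origin_mm = vol$grid$origin, spacing_mm = vol$grid$spacing,
                       role = vol$role), sidecar_path(path))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_input("missing file: ", path)
  img <- RNifti::readNifti(path)
  meta <- read_json_file(sidecar_path(path))
  arr <- array(as.numeric(img), dim(img))
  grid <- grid3d(dim(arr), as.numeric(meta$spacing_mm), as.numeric(meta$origin_mm))
  volume3d(grid, arr, role = meta$role)
}

#' Write / read a binary mask as NIfTI (unsigned 8-bit)
#'
#' @param m a [roi_mask()].
#' @param path output path; sidecar as in [write_volume()].
#' @return `read_mask` returns a [roi_mask()].
#' @export
write_mask <- function(m, path) {
  img <- RNifti::asNifti(array(as.integer(m$mask), m$grid$shape),
                         pixdim = m$grid$spacing, datatype = "uint8")
  RNifti::writeNifti(img, path)
  write_json_file(list(origin_mm = m$grid$origin, spacing_mm = m$grid$spacing,
                       name = m$name), sidecar_path(path))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_input("missing file: ", path)
  img <- RNifti::readNifti(path)
  meta <- read_json_file(sidecar_path(path))
  arr <- array(as.numeric(img) != 0, dim(img))
  grid <- grid3d(dim(arr), as.numeric(meta$spacing_mm), as.numeric(meta$origin_mm))
  roi_mask(grid, arr, name = meta$name)
}

#' Write / read a 3-D deformation field as NIfTI
#'
#' Stored as a 4-D image whose fourth dimension holds the x/y/z displacement
#' components in mm.
#'
#' @param dvf a [dvf3d()].
#' @param path output path; sidecar as in [write_volume()].
#' @return `read_dvf` returns a [dvf3d()].
#' @export
write_dvf <- function(dvf, path) {
  img <- RNifti::asNifti(dvf$vectors, pixdim = dvf$grid$spacing)
  RNifti::writeNifti(img, path)
  write_json_file(list(origin_mm = dvf$grid$origin, spacing_mm = dvf$grid$spacing,
                       components = "xyz displacement (mm), planning to daily"),
                  sidecar_path(path))
  invisible(path)
}

#' @rdname write_dvf
#' @export
read_dvf <- function(path) {
  if (!file.exists(path)) stop_input("missing file: ", path)
  img <- RNifti::readNifti(path)
  meta <- read_json_file(sidecar_path(path))
  arr <- array(as.numeric(img), dim(img))
  grid <- grid3d(dim(arr)[1:3], as.numeric(meta$spacing_mm), as.numeric(meta$origin_mm))
  dvf3d(grid, arr)
}

#' Write / read a fluence map as CSV with a JSON geometry sidecar
#'
#' @param f a [fluence_grid()].
#' @param path output CSV path (pixels as a matrix, x along rows); the
#'   sidecar `<path>.json` carries `spacing_mm`, `origin_mm`, `shape` and
#'   `beam_id`.
#' @return `read_fluence` returns a [fluence_grid()].
#' @export
write_fluence <- function(f, path) {
  utils::write.table(f$intensity, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  write_json_file(list(spacing_mm = f$plane$spacing, origin_mm = f$plane$origin,
                       shape = f$plane$shape, beam_id = f$beam_id),
                  sidecar_path(path))
  invisible(path)
}

#' @rdname write_fluence
#' @export
read_fluence <- function(path) {
  if (!file.exists(path)) stop_input("missing file: ", path)
  meta <- read_json_file(sidecar_path(path))
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  plane <- plane_grid(meta$shape, as.numeric(meta$spacing_mm), as.numeric(meta$origin_mm))
  fluence_grid(plane, m, beam_id = meta$beam_id)
}

#' Write / read a 2-D BEV deformation field
#'
#' Writes `<prefix>_vx.csv`, `<prefix>_vy.csv`, `<prefix>_coverage.csv` and
#' a JSON sidecar `<prefix>.json` with plane geometry and beam id.
#'
#' @param d a [dvf2d()].
#' @param prefix path prefix.
#' @return `read_dvf2d` returns a [dvf2d()].
#' @export
write_dvf2d <- function(d, prefix) {
  utils::write.table(d$vx, paste0(prefix, "_vx.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(d$vy, paste0(prefix, "_vy.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(d$coverage, paste0(prefix, "_coverage.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  write_json_file(list(spacing_mm = d$plane$spacing, origin_mm = d$plane$origin,
                       shape = d$plane$shape, beam_id = d$beam_id),
                  paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_dvf2d
#' @export
read_dvf2d <- function(prefix) {
  meta <- read_json_file(paste0(prefix, ".json"))
  rd <- function(sfx) {
    m <- as.matrix(utils::read.table(paste0(prefix, sfx), sep = ",", header = FALSE))
    dimnames(m) <- NULL
    m
  }
  plane <- plane_grid(meta$shape, as.numeric(meta$spacing_mm), as.numeric(meta$origin_mm))
  dvf2d(plane, rd("_vx.csv"), rd("_vy.csv"), rd("_coverage.csv"),
        beam_id = meta$beam_id)
}

#' Write / read beam descriptions as JSON
#'
#' Schema per beam: `{beam_id, gantry_angle_deg, collimator_angle_deg,
#' SAD_mm, isocenter_mm: [x, y, z]}`.
#'
#' @param beams list of [beam_geometry()].
#' @param path JSON path.
#' @return `read_beams` returns a list of [beam_geometry()].
#' @export
write_beams <- function(beams, path) {
  write_json_file(lapply(beams, function(b)
    list(beam_id = b$beam_id, gantry_angle_deg = b$gantry_angle,
         collimator_angle_deg = b$collimator_angle, SAD_mm = b$SAD,
         isocenter_mm = b$isocenter)), path)
  invisible(path)
}

#' @rdname write_beams
#' @export
read_beams <- function(path) {
  raw <- read_json_file(path)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(b)
    beam_geometry(gantry_angle = as.numeric(b$gantry_angle_deg),
                  SAD = as.numeric(b$SAD_mm),
                  isocenter = as.numeric(unlist(b$isocenter_mm)),
                  collimator_angle = as.numeric(b$collimator_angle_deg),
                  beam_id = as.character(b$beam_id)))
}

#' Write / read an aperture plan as JSON
#'
#' @param plan an [aperture_plan()].
#' @param path JSON path.
#' @return `read_plan` returns an [aperture_plan()].
#' @export
write_plan <- function(plan, path) {
  write_json_file(list(
    beam_id = plan$beam_id, jaws_mm = as.list(plan$jaws),
    leaf_width_mm = plan$leaf_width, y0_mm = plan$y0, n_pairs = plan$n_pairs,
    flags = as.list(plan$flags),
    segments = lapply(plan$segments, function(s)
      list(left_mm = s$left, right_mm = s$right, weight = s$weight))), path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  raw <- read_json_file(path)
  segs <- lapply(seq_len(if (is.data.frame(raw$segments)) nrow(raw$segments)
                         else length(raw$segments)), function(i) {
    s <- if (is.data.frame(raw$segments)) raw$segments[i, ] else raw$segments[[i]]
    list(left = as.numeric(unlist(s$left_mm)), right = as.numeric(unlist(s$right_mm)),
         weight = as.numeric(s$weight))
  })
  aperture_plan(raw$beam_id, unlist(raw$jaws_mm), raw$leaf_width_mm, raw$y0_mm,
                raw$n_pairs, segs, flags = as.character(unlist(raw$flags)))
}

#' Write / read a contour set as JSON
#'
#' @param c a [contour_set()].
#' @param path JSON path.
#' @return `read_contours` returns a [contour_set()].
#' @export
write_contours <- function(c, path) {
  write_json_file(list(
    structure_name = c$structure_name, slice_axis = c$slice_axis,
    slices = lapply(c$slices, function(polys)
      lapply(polys, function(p) unname(as.matrix(p))))), path)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop_input("missing file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- lapply(raw$slices, function(polys)
    lapply(polys, function(p)
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))))
  contour_set(raw$structure_name, slices, slice_axis = raw$slice_axis)
}
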