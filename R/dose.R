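#' Primary-beam dose computation
#'
#' Deliberately simple forward engine for plan comparison: for each voxel
#' and beam, the dose contribution is the fluence at the voxel's divergent
#' projection onto the isocenter plane (bilinear), attenuated by
#' `exp(-mu * radiological path length)` from the beam's entry into the
#' volume, times the inverse-square factor `(SAD / (SAD - z))^2` relative to
#' the isocenter.  Contributions are summed over beams.  The engine is
#' linear in the fluence, geometrically faithful and deterministic; it makes
#' no claim to scatter or buildup realism.
#'
#' @param plans list of beam entries; each entry is a list with `beam` (a
#'   [beam_geometry()]) and either `fluence` (a [fluence_grid()]) or `plan`
#'   (an [aperture_plan()], reconstructed on `params$plane`).
#' @param density a [volume3d()] of relative electron density.
#' @param params list: `mu_per_mm` (linear attenuation per mm of unit-density
#'   material, default 5e-4), `plane` (needed only for aperture-plan
#'   entries).
#' @return A [volume3d()] with role `"dose"` (Gy up to calibration).
#' @export
compute_dose <- function(plans, density, params = list()) {
  if (length(plans) == 0L) stop_input("compute_dose: empty beam list")
  mu <- if (is.null(params$mu_per_mm)) 5e-4 else params$mu_per_mm
  grid <- density$grid
  total <- numeric(prod(grid$shape))
  for (entry in plans) {
    beam <- entry$beam
    if (is.null(beam)) stop_input("compute_dose: each entry needs a 'beam'")
    f <- entry$fluence
    if (is.null(f)) {
      if (is.null(entry$plan) || is.null(params$plane))
        stop_input("compute_dose: aperture-plan entries need params$plane")
      f <- reconstruct_fluence(entry$plan, params$plane)
    }
    total <- total + cpp_dose_beam(
      as.numeric(density$values), grid$shape, grid$spacing, grid$origin,
      beam_axes(beam), beam$isocenter, beam$SAD,
      f$intensity, f$plane$spacing, f$plane$origin, mu)
  }
  volume3d(grid, array(total, grid$shape), role = "dose")
}

#' Cumulative dose-volume histogram
#'
#' @param dose a [volume3d()] with role `"dose"`.
#' @param roi a non-empty [roi_mask()] on the same grid.
#' @param bins number of dose bins for the exported curve (metrics in
#'   [dvh_metrics()] do not use the binning).
#' @return An object of class `dvh_curve`: `structure_name`, `dose_edges`
#'   (ascending, Gy, starting at 0) and `cumulative_volume_fraction`
#'   (non-increasing, starting at 1).
#' @export
compute_dvh <- function(dose, roi, bins = 100) {
  if (!same_grid(dose$grid, roi$grid))
    stop_input("compute_dvh: dose and ROI must share a grid")
  d <- dose$values[roi$mask]
  if (length(d) == 0L) stop_input("compute_dvh: empty ROI")
  edges <- seq(0, max(d, 1e-12), length.out = bins + 1)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  structure(list(structure_name = roi$name, dose_edges = edges,
                 cumulative_volume_fraction = frac),
            class = "dvh_curve")
}

#' Dose-volume metrics for one structure
#'
#' Dq is the dose received by the hottest q percent of the structure,
#' computed by linear interpolation on the sorted voxel doses (no binning);
#' Vx is the percentage of the structure receiving at least x Gy.  The
#' homogeneity index HI is D5/D95.
#'
#' @param dose a [volume3d()] (Gy).
#' @param roi a non-empty [roi_mask()].
#' @param prescription prescription dose in Gy (defines V100).
#' @param vx_thresholds numeric Gy thresholds for the Vx columns.
#' @return A list with `D95`, `D5`, `V100_pct`, `HI`, `mean`, `max` and `Vx`
#'   (named vector, percent).
#' @export
dvh_metrics <- function(dose, roi, prescription, vx_thresholds = c(5, 20, 30)) {
  if (!same_grid(dose$grid, roi$grid))
    stop_input("dvh_metrics: dose and ROI must share a grid")
  d <- dose$values[roi$mask]
  if (length(d) == 0L) stop_input("dvh_metrics: empty ROI")
  dq <- function(q) unname(quantile(d, probs = 1 - q / 100, type = 7))
  D95 <- dq(95); D5 <- dq(5)
  ## volume thresholds use a 1e-9 relative tolerance so that voxels sitting
  ## exactly at a threshold (e.g. the calibration voxel at the prescription)
  ## are counted stably against float round-off
  vfrac <- function(x) 100 * mean(d >= x - 1e-9 * max(abs(x), 1))
  vx <- vapply(vx_thresholds, vfrac, numeric(1))
  names(vx) <- paste0("V", vx_thresholds)
  list(D95 = D95, D5 = D5,
       V100_pct = vfrac(prescription),
       HI = if (D95 > 0) D5 / D95 else NA_real_,
       mean = mean(d), max = max(d), Vx = vx)
}

#' Couch shift maximising target overlap
#'
#' Exhaustive search over integer multiples of `step` within
#' `search_radius`, maximising the number of voxels in which the shifted
#' planning target overlaps the daily target (the shift is applied to the
#' planning mask on the voxel lattice, so sub-voxel steps cannot improve the
#' overlap count).  Ties are broken by the smallest shift norm, then
#' lexicographically.
#'
#' @param ctv_plan,ctv_daily non-empty [roi_mask()]s on a shared grid.
#' @param search_radius search radius, mm.
#' @param step search step, mm; defaults to the voxel spacing per axis.
#' @return 3-vector shift in mm, with attribute `"overlap"` (voxel count).
#'   A zero best overlap is reported via a warning.
#' @export
repositioning_shift <- function(ctv_plan, ctv_daily, search_radius = 15, step = NULL) {
  if (!same_grid(ctv_plan$grid, ctv_daily$grid))
    stop_input("repositioning_shift: masks must share a grid")
  if (!any(ctv_plan$mask) || !any(ctv_daily$mask))
    stop_input("repositioning_shift: masks must be non-empty")
  sp <- ctv_plan$grid$spacing
  if (is.null(step)) step <- sp
  if (length(step) == 1L) step <- rep(step, 3)
  cand <- lapply(1:3, function(k) {
    kk <- floor(search_radius / step[k])
    (-kk:kk) * step[k]
  })
  shifts <- as.matrix(expand.grid(cand[[1]], cand[[2]], cand[[3]]))
  shifts <- shifts[sqrt(rowSums(shifts^2)) <= search_radius + 1e-9, , drop = FALSE]
  sh <- ctv_plan$grid$shape
  ijk <- which(ctv_plan$mask, arr.ind = TRUE) - 1L   # 0-based
  daily <- ctv_daily$mask
  overlaps <- integer(nrow(shifts))
  for (r in seq_len(nrow(shifts))) {
    off <- round(shifts[r, ] / sp)
    i <- ijk[, 1] + off[1]; j <- ijk[, 2] + off[2]; k <- ijk[, 3] + off[3]
    ok <- i >= 0 & i < sh[1] & j >= 0 & j < sh[2] & k >= 0 & k < sh[3]
    if (!any(ok)) next
    lin <- 1 + i[ok] + sh[1] * (j[ok] + sh[2] * k[ok])
    overlaps[r] <- sum(daily[lin])
  }
  norms <- sqrt(rowSums(shifts^2))
  ord <- order(-overlaps, norms, shifts[, 1], shifts[, 2], shifts[, 3])
  best <- ord[1]
  if (overlaps[best] == 0L)
    warning("repositioning_shift: no overlap found within the search radius")
  out <- as.numeric(shifts[best, ])
  attr(out, "overlap") <- overlaps[best]
  out
}

## Shift a beam's isocenter (couch correction): the whole beam geometry,
## source and fluence plane move with the isocenter.
shift_beam <- function(beam, shift) {
  beam$isocenter <- beam$isocenter + shift
  beam
}

#' Three-scenario plan comparison on a daily anatomy
#'
#' Evaluates, on the daily anatomy, (1) the original plan at the planned
#' isocenter, (2) the original plan with the isocenter moved by the couch
#' shift maximising CTV overlap (IGRT repositioning), and (3) the
#' intensity-field-projection plan: the 3-D deformation field is projected
#' into each beam's-eye view, the original fluence is warped along it,
#' jaws are re-fitted and the warped fluence is re-sequenced into MLC
#' segments whose reconstructed fluence is what the dose engine sees.
#'
#' @param planning list with `density` (a [volume3d()]) and `masks` (named
#'   list of [roi_mask()]s containing at least `ctv` and the projection ROI).
#' @param daily same layout for the anatomy of the day.
#' @param dvf a [dvf3d()] mapping planning to daily anatomy.
#' @param beams list of [beam_geometry()].
#' @param fluences list of calibrated [fluence_grid()]s, one per beam.
#' @param config list overriding defaults: `prescription` (Gy, 60),
#'   `mu_per_mm` (5e-4), `projection_roi` ("ptv"), `fill_mode` ("nearest":
#'   the projected field is extended continuously beyond the ROI shadow so
#'   the push warp does not fold static zero-vector pixels into the moving
#'   aperture edge),
#'   `warp_mode` ("push"), `conserve_total` (FALSE), `levels` (10),
#'   `leaf_width` (row spacing), `jaw_margin` (0), `structures`
#'   (evaluated structures, default c("ctv","lungs","cord")),
#'   `vx_thresholds` (c(5,20,30)), `reposition_radius` (15),
#'   `reposition_step` (voxel spacing).
#' @return A list with `metrics` (data.frame: one row per scenario and
#'   structure), `doses` (per-scenario [volume3d()]s), `shift` (the couch
#'   shift used in scenario 2), `dvf2d`, `warped_fluences` and `plans` (the
#'   per-beam [aperture_plan()]s of scenario 3).
#' @export
compare_scenarios <- function(planning, daily, dvf, beams, fluences,
                              config = list()) {
  cfg <- modifyList(list(
    prescription = 60, mu_per_mm = 5e-4, projection_roi = "ptv",
    fill_mode = "nearest", warp_mode = "push", conserve_total = FALSE,
    levels = 10, leaf_width = NULL, jaw_margin = 0,
    structures = c("ctv", "lungs", "cord"), vx_thresholds = c(5, 20, 30),
    reposition_radius = 15, reposition_step = NULL), config)
  if (length(beams) != length(fluences))
    stop_input("compare_scenarios: need one fluence per beam")
  roi <- planning$masks[[cfg$projection_roi]]
  if (is.null(roi))
    stop_input("compare_scenarios: projection ROI '", cfg$projection_roi,
               "' missing from planning masks")
  dose_params <- list(mu_per_mm = cfg$mu_per_mm)

  ## scenario 1: original plan, planned isocenter, daily anatomy
  plans1 <- Map(function(b, f) list(beam = b, fluence = f), beams, fluences)
  dose_orig <- compute_dose(plans1, daily$density, dose_params)

  ## scenario 2: couch repositioning by maximum CTV overlap
  shift <- repositioning_shift(planning$masks$ctv, daily$masks$ctv,
                               search_radius = cfg$reposition_radius,
                               step = cfg$reposition_step)
  plans2 <- Map(function(b, f) list(beam = shift_beam(b, shift), fluence = f),
                beams, fluences)
  dose_repo <- compute_dose(plans2, daily$density, dose_params)

  ## scenario 3: intensity field projection
  d2s <- list(); warped <- list(); aplans <- list()
  for (i in seq_along(beams)) {
    d2 <- project_dvf_to_bev(dvf, roi, beams[[i]], fluences[[i]]$plane)
    d2 <- fill_uncovered(d2, mode = cfg$fill_mode)
    wf <- warp_fluence(fluences[[i]], d2, mode = cfg$warp_mode,
                       conserve_total = cfg$conserve_total)
    ap <- sequence_fluence(wf, leaf_width = cfg$leaf_width,
                           levels = cfg$levels, jaw_margin = cfg$jaw_margin)
    d2s[[i]] <- d2; warped[[i]] <- wf; aplans[[i]] <- ap
  }
  plans3 <- Map(function(b, ap, f)
    list(beam = b, fluence = reconstruct_fluence(ap, f$plane)),
    beams, aplans, fluences)
  dose_ifp <- compute_dose(plans3, daily$density, dose_params)

  doses <- list(original = dose_orig, repositioning = dose_repo, ifp = dose_ifp)
  rows <- list()
  for (sc in names(doses)) {
    for (st in cfg$structures) {
      msk <- daily$masks[[st]]
      if (is.null(msk)) stop_input("compare_scenarios: structure '", st, "' missing")
      mm <- dvh_metrics(doses[[sc]], msk, cfg$prescription, cfg$vx_thresholds)
      row <- data.frame(scenario = sc, structure = st, D95 = mm$D95, D5 = mm$D5,
                        V100_pct = mm$V100_pct, HI = mm$HI, mean = mm$mean,
                        max = mm$max, stringsAsFactors = FALSE)
      for (nm in names(mm$Vx)) row[[nm]] <- mm$Vx[[nm]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  list(metrics = do.call(rbind, rows), doses = doses, shift = shift,
       dvf2d = d2s, warped_fluences = warped, plans = aplans)
}
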