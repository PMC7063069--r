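#' Step-and-shoot aperture plan
#'
#' Jaw settings plus an ordered list of weighted MLC segments realising a
#' fluence map.  Leaf pairs travel along the plane x axis and are stacked
#' along y; `y0` is the lower edge of the first leaf pair.
#'
#' @param beam_id label.
#' @param jaws named numeric (x1, x2, y1, y2), mm at the isocenter.
#' @param leaf_width leaf width at the isocenter, mm.
#' @param y0 lower y edge of leaf pair 1, mm.
#' @param n_pairs number of leaf pairs.
#' @param segments list of `list(left, right, weight)`; `left`/`right` are
#'   per-pair leaf positions (mm, `left <= right`), `weight` >= 0.
#' @param flags character vector of advisory flags (e.g. unenforced delivery
#'   constraints).
#' @return An object of class `aperture_plan`.
#' @export
aperture_plan <- function(beam_id, jaws, leaf_width, y0, n_pairs, segments,
                          flags = character(0)) {
  jaws <- as.numeric(jaws)
  if (length(jaws) != 4L || jaws[1] >= jaws[2] || jaws[3] >= jaws[4])
    stop_input("aperture_plan: jaws must satisfy x1 < x2 and y1 < y2")
  if (length(segments) < 1L)
    stop_input("aperture_plan: at least one segment required")
  for (s in segments) {
    if (length(s$left) != n_pairs || length(s$right) != n_pairs)
      stop_input("aperture_plan: leaf position vectors must have one entry per pair")
    if (any(s$left > s$right + 1e-9))
      stop_input("aperture_plan: left leaf beyond right leaf")
    if (s$weight < 0) stop_input("aperture_plan: segment weights must be >= 0")
  }
  structure(list(beam_id = beam_id, jaws = stats::setNames(jaws, c("x1", "x2", "y1", "y2")),
                 leaf_width = leaf_width, y0 = y0, n_pairs = as.integer(n_pairs),
                 segments = segments, flags = flags),
            class = "aperture_plan")
}

#' Fit jaw settings around the open part of a fluence map
#'
#' Tightest rectangle containing every pixel brighter than the open
#' threshold, expanded by `margin` and snapped outward to pixel boundaries.
#'
#' @param f a [fluence_grid()]; must not be all zero.
#' @param margin extra opening beyond the open region, mm (>= 0).
#' @param open_threshold fraction of the maximum counting as open.
#' @return Named numeric (x1, x2, y1, y2), mm.
#' @export
fit_jaws <- function(f, margin = 0, open_threshold = 0.01) {
  if (all(f$intensity == 0)) stop_input("fit_jaws: all-zero fluence")
  if (margin < 0) stop_input("fit_jaws: margin must be >= 0")
  open <- f$intensity > open_threshold * max(f$intensity)
  ij <- which(open, arr.ind = TRUE)
  ax <- plane_axes(f$plane)
  sx <- f$plane$spacing[1]; sy <- f$plane$spacing[2]
  x1 <- min(ax$x[ij[, 1]]) - sx / 2 - margin
  x2 <- max(ax$x[ij[, 1]]) + sx / 2 + margin
  y1 <- min(ax$y[ij[, 2]]) - sy / 2 - margin
  y2 <- max(ax$y[ij[, 2]]) + sy / 2 + margin
  snap_out <- function(v, o, s, up) {
    edge0 <- o - s / 2
    k <- (v - edge0) / s
    edge0 + (if (up) ceiling(k - 1e-9) else floor(k + 1e-9)) * s
  }
  c(x1 = snap_out(x1, f$plane$origin[1], sx, FALSE),
    x2 = snap_out(x2, f$plane$origin[1], sx, TRUE),
    y1 = snap_out(y1, f$plane$origin[2], sy, FALSE),
    y2 = snap_out(y2, f$plane$origin[2], sy, TRUE))
}

## Row-wise sweep decomposition of one quantised profile (integer units).
## Returns left/right leaf edge positions for each of `nseg` unit segments;
## pairs beyond the row's own complexity are parked closed at `park`.
sweep_row <- function(h, x, sx, nseg, park) {
  rises <- h - c(0, h[-length(h)])              # increase entering pixel i
  falls <- h - c(h[-1], 0)                      # decrease after pixel i
  left_edges <- rep(x - sx / 2, pmax(rises, 0))
  right_edges <- rep(x + sx / 2, pmax(falls, 0))
  left_edges <- sort(left_edges); right_edges <- sort(right_edges)
  nrow_seg <- length(left_edges)
  L <- rep(park, nseg); R <- rep(park, nseg)
  if (nrow_seg > 0) {
    L[seq_len(nrow_seg)] <- left_edges
    R[seq_len(nrow_seg)] <- right_edges
  }
  list(left = L, right = R, complexity = nrow_seg)
}

#' Sequence a fluence map into step-and-shoot MLC segments
#'
#' Quantises the map to `levels` uniform intensity levels (step =
#' max/levels, rounding to the nearest level) and decomposes each leaf-pair
#' row with the classical unidirectional sweep: the k-th segment's left leaf
#' edge sits at the row's k-th intensity rise and its right leaf edge at the
#' k-th fall.  Every segment carries weight = one quantisation step, so the
#' total weight equals the largest row's sum of positive intensity
#' increments (the minimal-MU sweep bound), and
#' [reconstruct_fluence()] of the result reproduces the quantised map
#' exactly (for unimodal and general rows alike).  The number of segments is
#' at most `levels` when every row profile is unimodal.
#'
#' @param f a [fluence_grid()]; must not be all zero.
#' @param leaf_width leaf width, mm; must be an integer multiple of the
#'   fluence row spacing (rows are averaged within each leaf pair when the
#'   multiple exceeds 1).
#' @param levels number of quantisation levels (>= 1).
#' @param jaw_margin margin passed to [fit_jaws()], mm.
#' @return An [aperture_plan()].
#' @export
sequence_fluence <- function(f, leaf_width = NULL, levels = 10, jaw_margin = 0) {
  if (levels < 1) stop_input("sequence_fluence: levels must be >= 1")
  if (all(f$intensity == 0)) stop_input("sequence_fluence: all-zero fluence (no open field)")
  sx <- f$plane$spacing[1]; sy <- f$plane$spacing[2]
  if (is.null(leaf_width)) leaf_width <- sy
  m <- leaf_width / sy
  if (abs(m - round(m)) > 1e-9 || m < 1)
    stop_input("sequence_fluence: leaf_width must be an integer multiple of the row spacing")
  m <- as.integer(round(m))
  ny <- f$plane$shape[2]
  n_pairs <- ceiling(ny / m)
  ## leaf-pair profiles: mean over the fluence rows a pair covers
  prof <- matrix(0, f$plane$shape[1], n_pairs)
  for (p in seq_len(n_pairs)) {
    rows <- ((p - 1) * m + 1):min(p * m, ny)
    prof[, p] <- rowMeans(f$intensity[, rows, drop = FALSE])
  }
  step <- max(prof) / levels
  h <- matrix(as.integer(round(prof / step)), nrow(prof), n_pairs)
  if (all(h == 0)) stop_input("sequence_fluence: quantised fluence is empty")
  ax <- plane_axes(f$plane)
  jaws <- fit_jaws(f, margin = jaw_margin)
  park <- jaws[["x1"]]
  nseg <- max(vapply(seq_len(n_pairs), function(p) {
    r <- h[, p] - c(0L, h[-nrow(h), p]); sum(pmax(r, 0L))
  }, integer(1)))
  rows <- lapply(seq_len(n_pairs), function(p) sweep_row(h[, p], ax$x, sx, nseg, park))
  segments <- lapply(seq_len(nseg), function(k) {
    list(left = vapply(rows, function(r) r$left[k], numeric(1)),
         right = vapply(rows, function(r) r$right[k], numeric(1)),
         weight = step)
  })
  y0 <- f$plane$origin[2] - sy / 2
  flags <- character(0)
  if (nseg > levels) flags <- c(flags, "segments_exceed_levels_nonunimodal")
  aperture_plan(f$beam_id, jaws, leaf_width, y0, n_pairs, segments, flags)
}

#' Reconstruct the fluence delivered by an aperture plan
#'
#' Sums, over segments, weight times the indicator that a pixel centre lies
#' strictly inside both the segment's leaf opening and the jaws.
#'
#' @param plan an [aperture_plan()].
#' @param plane a [plane_grid()] for the output map.
#' @return A [fluence_grid()].
#' @export
reconstruct_fluence <- function(plan, plane) {
  ax <- plane_axes(plane)
  nx <- plane$shape[1]; ny <- plane$shape[2]
  out <- matrix(0, nx, ny)
  pair_of_row <- pmin(pmax(floor((ax$y - plan$y0) / plan$leaf_width), 0), plan$n_pairs - 1) + 1L
  in_jaw_x <- ax$x > plan$jaws[["x1"]] & ax$x < plan$jaws[["x2"]]
  in_jaw_y <- ax$y > plan$jaws[["y1"]] & ax$y < plan$jaws[["y2"]]
  row_in_band <- ax$y >= plan$y0 & ax$y < plan$y0 + plan$n_pairs * plan$leaf_width
  for (s in plan$segments) {
    for (j in seq_len(ny)) {
      if (!in_jaw_y[j] || !row_in_band[j]) next
      p <- pair_of_row[j]
      open <- in_jaw_x & ax$x > s$left[p] & ax$x < s$right[p]
      out[open, j] <- out[open, j] + s$weight
    }
  }
  fluence_grid(plane, out, beam_id = plan$beam_id)
}
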