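# Distortion statistics: plane and 3D point distortions, cumulative-radius
# summaries, threshold fractions, histograms, mark-point tracking through
# the slice stack, and vector-field export.

#' Plane distortion between a reference and an imaged point
#'
#' Euclidean in-plane distance
#' `sqrt((x1 - x)^2 + (y1 - y)^2)` between the reference (CT-role)
#' coordinates and the registered imaged (MR-role) coordinates of a control
#' point. Vectorized.
#'
#' @param x,y Reference coordinates (mm).
#' @param x1,y1 Imaged coordinates (mm).
#' @return Distortion in mm.
#' @examples
#' plane_distortion(0, 0, 3, 4)  # 5
#' @export
plane_distortion <- function(x, y, x1, y1) {
  stopifnot(is.finite(x), is.finite(y), is.finite(x1), is.finite(y1))
  sqrt((x1 - x)^2 + (y1 - y)^2)
}

#' 3D distortion between a reference and an imaged point
#'
#' `sqrt((x1 - x)^2 + (y1 - y)^2 + (z1 - z)^2)`; with `z1 = z` it reduces
#' to [plane_distortion()]. Vectorized.
#'
#' @param x,y,z Coordinates in the plane closer to the foot (mm).
#' @param x1,y1,z1 Coordinates in the plane closer to the head (mm).
#' @return Distortion in mm.
#' @examples
#' distortion_3d(0, 0, 0, 1, 2, 2)  # 3
#' @export
distortion_3d <- function(x, y, z, x1, y1, z1) {
  stopifnot(is.finite(x), is.finite(y), is.finite(z),
            is.finite(x1), is.finite(y1), is.finite(z1))
  sqrt((x1 - x)^2 + (y1 - y)^2 + (z1 - z)^2)
}

#' Cumulative-radius distortion summary
#'
#' For each radius `r` in `radii_mm`, summarizes the plane distortion of
#' all control points whose reference distance from the center is at most
#' `r` — cumulative discs, not annuli, so the largest radius covering every
#' point reproduces the whole-phantom mean and SD exactly. SD is the
#' sample standard deviation (n - 1 denominator).
#'
#' @param correspondences Data frame with columns `x`, `y`, `plane_d_mm`
#'   (e.g. from [match_nodes()]).
#' @param radii_mm Radii of the cumulative discs (mm).
#' @return Data frame of class `summary_table`: `radius_mm`, `n`,
#'   `mean_mm`, `sd_mm`, `max_mm`. Empty discs are omitted with a warning.
#' @export
radial_summary <- function(correspondences, radii_mm = c(50, 100, 150, 200)) {
  stopifnot(nrow(correspondences) > 0L)
  r <- sqrt(correspondences$x^2 + correspondences$y^2)
  rows <- lapply(radii_mm, function(rad) {
    d <- correspondences$plane_d_mm[r <= rad + 1e-9]
    if (length(d) == 0L) {
      warning(sprintf("no control points within %g mm; row omitted", rad))
      return(NULL)
    }
    data.frame(radius_mm = rad, n = length(d), mean_mm = mean(d),
               sd_mm = if (length(d) > 1L) stats::sd(d) else 0,
               max_mm = max(d))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary_table", class(out))
  out
}

#' Fraction of control points below a distortion threshold
#'
#' @param correspondences Correspondence data.frame (or a numeric vector of
#'   distortion values).
#' @param threshold_mm Threshold, default 2 mm (the clinical QA gate).
#' @return Fraction in `[0, 1]` of points with distortion strictly below
#'   the threshold.
#' @export
fraction_below <- function(correspondences, threshold_mm = 2) {
  d <- if (is.numeric(correspondences)) correspondences
  else correspondences$plane_d_mm
  stopifnot(length(d) > 0L)
  mean(d < threshold_mm)
}

#' Histogram of distortion values
#'
#' Counts per half-open bin `[k * bin, (k + 1) * bin)`; counts sum to the
#' number of points.
#'
#' @inheritParams fraction_below
#' @param bin_mm Bin width (mm).
#' @return Data frame `bin_lo_mm`, `bin_hi_mm`, `count`.
#' @export
distortion_histogram <- function(correspondences, bin_mm = 0.5) {
  stopifnot(bin_mm > 0)
  d <- if (is.numeric(correspondences)) correspondences
  else correspondences$plane_d_mm
  k <- floor(d / bin_mm)
  kk <- seq.int(0L, max(k))
  counts <- vapply(kk, function(i) sum(k == i), integer(1))
  data.frame(bin_lo_mm = kk * bin_mm, bin_hi_mm = (kk + 1) * bin_mm,
             count = counts)
}

#' Mark points for 3D distortion tracking
#'
#' Selects points at the requested radii and angles; angles are measured
#' clockwise from the +y axis (`0` degrees = +y, `90` = +x), so
#' `(x, y) = (r sin(theta), r cos(theta))`. Points removed by the phantom's
#' stability cut — those with `y <= -cut_chord_offset_mm`, i.e. the
#' 180-degree point at 15 cm with the defaults — are excluded, leaving 11
#' of the 12 requested default points.
#'
#' @param radii_mm Radii (mm), default 50/100/150.
#' @param angles_deg Angles clockwise from +y (degrees).
#' @param cut_chord_offset_mm Cut offset used for the exclusion rule.
#' @return Data frame `label`, `radius_mm`, `angle_deg`, `x_mm`, `y_mm`.
#' @export
mark_points <- function(radii_mm = c(50, 100, 150),
                        angles_deg = c(0, 90, 180, 270),
                        cut_chord_offset_mm = 150) {
  g <- expand.grid(angle_deg = angles_deg, radius_mm = radii_mm)
  th <- g$angle_deg * pi / 180
  out <- data.frame(label = sprintf("r%g_a%g", g$radius_mm, g$angle_deg),
                    radius_mm = g$radius_mm, angle_deg = g$angle_deg,
                    x_mm = round(g$radius_mm * sin(th), 9),
                    y_mm = round(g$radius_mm * cos(th), 9))
  keep <- out$y_mm > -cut_chord_offset_mm + 1e-9
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Layer-selection rule: partition the foot-to-head slice stack into
# n_layers contiguous groups as equal as possible; the first selected layer
# is the most-foot slice, and every later group contributes its head-most
# member.
.select_layers <- function(n_slices, n_layers) {
  if (n_slices < n_layers)
    stop(sprintf("need at least %d slices, got %d", n_layers, n_slices),
         call. = FALSE)
  bounds <- floor(seq_len(n_layers) * n_slices / n_layers)  # group ends
  c(1L, bounds[-1L])
}

#' Track mark points through the slice stack
#'
#' Applies the 30-layer selection rule — the most-foot slice is the bottom
#' layer; each subsequent group of slices contributes the layer closest to
#' the head — and extracts, for every mark point, the registered imaged
#' coordinates of its nearest lattice node in each selected slice.
#'
#' @param slice_correspondences List of correspondence data.frames (one per
#'   slice, ordered foot to head, as from [match_nodes()]).
#' @param slice_z_mm Slice positions (mm), same length and order.
#' @param lattice A `node_lattice`.
#' @param marks Mark-point table from [mark_points()].
#' @param n_layers Number of layers to select (default 30).
#' @return Data frame `label`, `radius_mm`, `angle_deg`, `layer`,
#'   `slice_index`, `z_mm`, `x_mm`, `y_mm` (imaged coordinates; `NA` when
#'   the node was unmatched in that slice).
#' @export
track_slices <- function(slice_correspondences, slice_z_mm, lattice,
                         marks = mark_points(), n_layers = 30) {
  stopifnot(length(slice_correspondences) == length(slice_z_mm))
  sel <- .select_layers(length(slice_correspondences), n_layers)
  nodes <- lattice$nodes
  nearest <- vapply(seq_len(nrow(marks)), function(i) {
    d2 <- (nodes$x_mm - marks$x_mm[i])^2 + (nodes$y_mm - marks$y_mm[i])^2
    nodes$node_id[which.min(d2)]
  }, integer(1))
  out <- do.call(rbind, lapply(seq_along(sel), function(li) {
    ci <- sel[li]
    corr <- slice_correspondences[[ci]]
    idx <- match(nearest, corr$node_id)
    data.frame(label = marks$label, radius_mm = marks$radius_mm,
               angle_deg = marks$angle_deg, layer = li,
               slice_index = ci, z_mm = slice_z_mm[ci],
               x_mm = corr$x1[idx], y_mm = corr$y1[idx])
  }))
  rownames(out) <- NULL
  out
}

#' Summarize 3D mark-point distortion across selected layers
#'
#' For each consecutive pair of selected layers the 3D distortion is
#' computed with `(x, y, z)` from the foot-side layer and `(x1, y1, z1)`
#' from the head-side layer. By default `z` and `z1` are the slice
#' positions, so the head-foot term of a geometrically identical pair
#' equals the selected-layer spacing; `z_mode = "in_plane_only"` instead
#' sets the head-foot term to zero, isolating the in-plane coordinate
#' change between layers. Pairs in which the mark point was unmatched in
#' either layer are skipped (their count is reported in
#' `attr(, "skipped_pairs")`).
#'
#' @param profiles Output of [track_slices()].
#' @param z_mode `"slice_position"` (default) or `"in_plane_only"`.
#' @return Data frame of class `summary_table` with one row per mark point
#'   (`radius_mm`, `angle`, `mean_mm`, `sd_mm`, `n`) plus one `"average"`
#'   row per radius pooling all its pair values.
#' @export
mark_point_3d_summary <- function(profiles,
                                  z_mode = c("slice_position",
                                             "in_plane_only")) {
  z_mode <- match.arg(z_mode)
  stopifnot(nrow(profiles) > 0L)
  skipped <- 0L
  vals <- list()
  for (lab in unique(profiles$label)) {
    p <- profiles[profiles$label == lab, , drop = FALSE]
    p <- p[order(p$layer), , drop = FALSE]
    nf <- nrow(p) - 1L
    if (nf < 1L) next
    f <- seq_len(nf); h <- f + 1L
    dz <- if (z_mode == "slice_position") p$z_mm[h] - p$z_mm[f]
    else rep(0, nf)
    ok <- !is.na(p$x_mm[f]) & !is.na(p$x_mm[h])
    skipped <- skipped + sum(!ok)
    v <- distortion_3d(p$x_mm[f][ok], p$y_mm[f][ok], 0,
                       p$x_mm[h][ok], p$y_mm[h][ok], dz[ok])
    vals[[lab]] <- list(radius = p$radius_mm[1], angle = p$angle_deg[1],
                        v = v)
  }
  rows <- lapply(vals, function(e)
    data.frame(radius_mm = e$radius, angle = as.character(e$angle),
               mean_mm = mean(e$v),
               sd_mm = if (length(e$v) > 1) stats::sd(e$v) else 0,
               n = length(e$v)))
  out <- do.call(rbind, rows)
  for (rad in unique(out$radius_mm)) {
    pooled <- unlist(lapply(vals, function(e)
      if (e$radius == rad) e$v else NULL))
    out <- rbind(out,
                 data.frame(radius_mm = rad, angle = "average",
                            mean_mm = mean(pooled),
                            sd_mm = if (length(pooled) > 1)
                              stats::sd(pooled) else 0,
                            n = length(pooled)))
  }
  out <- out[order(out$radius_mm, out$angle != "average", out$angle), ]
  out <- out[order(out$radius_mm), ]
  rownames(out) <- NULL
  attr(out, "skipped_pairs") <- skipped
  class(out) <- c("summary_table", class(out))
  out
}

#' Export the distortion vector field
#'
#' Per-node table for quiver/scatter rendering: reference position,
#' displacement components and magnitude.
#'
#' @param correspondences Correspondence data.frame.
#' @return Data frame `x`, `y`, `dx`, `dy`, `d_mm`.
#' @export
export_field <- function(correspondences) {
  stopifnot(nrow(correspondences) > 0L)
  data.frame(x = correspondences$x, y = correspondences$y,
             dx = correspondences$x1 - correspondences$x,
             dy = correspondences$y1 - correspondences$y,
             d_mm = plane_distortion(correspondences$x, correspondences$y,
                                     correspondences$x1,
                                     correspondences$y1))
}
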