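# Simplified geometric dose-impact analysis. The full treatment-planning
# study (IMRT optimization, electron-return-effect physics) is outside
# what a distortion pipeline determines; this module isolates the purely
# geometric component: how displacing a region of interest by the measured
# distortion field changes its mean dose on a supplied dose grid.

#' Construct a 2D dose grid
#'
#' @param dose Numeric matrix of dose values (Gy), rows = y, cols = x,
#'   on the same raster convention as [image_volume()].
#' @param pixel_size_mm Voxel size (mm).
#' @param origin_mm (x, y) of the center of voxel `[1, 1]` (mm); default
#'   centers the grid on the isocenter.
#' @param prescription_gy Prescription dose (Gy).
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(dose, pixel_size_mm, origin_mm = NULL,
                      prescription_gy = 50) {
  stopifnot(is.matrix(dose), all(dose >= 0), pixel_size_mm > 0)
  if (is.null(origin_mm)) origin_mm <- -(dim(dose)[2:1] - 1) / 2 *
      pixel_size_mm
  structure(list(dose = dose, pixel_size_mm = pixel_size_mm,
                 origin_mm = as.numeric(origin_mm),
                 prescription_gy = prescription_gy),
            class = "dose_grid")
}

#' Square and disc regions of interest
#'
#' @param label ROI name.
#' @param x_mm,y_mm Center (mm).
#' @param half_mm Half side length of a square ROI (mm).
#' @param radius_mm Radius of a disc ROI (mm).
#' @return An `roi` object.
#' @export
roi_square <- function(label, x_mm, y_mm, half_mm) {
  stopifnot(half_mm > 0)
  structure(list(label = label, type = "square",
                 x_mm = x_mm, y_mm = y_mm, half_mm = half_mm),
            class = "roi")
}

#' @rdname roi_square
#' @export
roi_disc <- function(label, x_mm, y_mm, radius_mm) {
  stopifnot(radius_mm > 0)
  structure(list(label = label, type = "disc",
                 x_mm = x_mm, y_mm = y_mm, radius_mm = radius_mm),
            class = "roi")
}

#' Default region-of-interest layout
#'
#' The 14 square ROIs of the reporting layout plus a whole-phantom disc: a
#' central 2 x 2 cm square (`p`), and 1 x 1 cm squares at 5 cm (`p1-1..4`),
#' 10 cm (`p2-1..4`), 15 cm (`p3-1..3`) and 17 cm (`p4-1..2`) from the
#' center. Angular placement follows the mark-point convention (0/90/180/
#' 270 degrees clockwise from +y); positions lost to the stability cut are
#' dropped — the 180-degree position at 15 cm, and at the 17 cm edge ring
#' only the lateral 90/270-degree positions are retained.
#'
#' @param grid_inner_radius_mm Radius of the whole-phantom disc ROI.
#' @return List of 15 `roi` objects (14 squares and the `"phantom"` disc).
#' @export
default_rois <- function(grid_inner_radius_mm = 170) {
  ang <- function(a) a * pi / 180
  mk <- function(label, r, a, half)
    roi_square(label, round(r * sin(ang(a)), 9), round(r * cos(ang(a)), 9),
               half)
  rois <- list(roi_square("p", 0, 0, 10))
  a4 <- c(0, 90, 180, 270)
  for (i in 1:4) rois[[length(rois) + 1L]] <-
    mk(sprintf("p1-%d", i), 50, a4[i], 5)
  for (i in 1:4) rois[[length(rois) + 1L]] <-
    mk(sprintf("p2-%d", i), 100, a4[i], 5)
  a3 <- c(0, 90, 270)
  for (i in 1:3) rois[[length(rois) + 1L]] <-
    mk(sprintf("p3-%d", i), 150, a3[i], 5)
  a2 <- c(90, 270)
  for (i in 1:2) rois[[length(rois) + 1L]] <-
    mk(sprintf("p4-%d", i), 170, a2[i], 5)
  rois[[length(rois) + 1L]] <- roi_disc("phantom", 0, 0,
                                        grid_inner_radius_mm)
  rois
}

# Voxel weights (overlap fractions) of an ROI on a dose grid. Square ROIs
# get exact per-axis clamped overlap; disc ROIs use 4x4 subsampling.
.roi_weights <- function(grid, roi) {
  px <- grid$pixel_size_mm
  xs <- grid$origin_mm[1] + (seq_len(ncol(grid$dose)) - 1) * px
  ys <- grid$origin_mm[2] + (seq_len(nrow(grid$dose)) - 1) * px
  if (roi$type == "square") {
    ovl <- function(c0, lo, hi)
      pmax(pmin(c0 + px / 2, hi) - pmax(c0 - px / 2, lo), 0) / px
    wx <- ovl(xs, roi$x_mm - roi$half_mm, roi$x_mm + roi$half_mm)
    wy <- ovl(ys, roi$y_mm - roi$half_mm, roi$y_mm + roi$half_mm)
    w <- outer(wy, wx)
  } else {
    off <- ((1:4) - 2.5) / 4 * px
    w <- matrix(0, nrow(grid$dose), ncol(grid$dose))
    for (ox in off) for (oy in off) {
      inside <- outer((ys + oy - roi$y_mm)^2, (xs + ox - roi$x_mm)^2, "+") <=
        roi$radius_mm^2
      w <- w + inside
    }
    w <- w / 16
  }
  if (sum(w) <= 0) stop("ROI '", roi$label, "' lies outside the dose grid",
                        call. = FALSE)
  # reject ROIs extending beyond the grid (lost area)
  area_vox <- sum(w) * px^2
  area_roi <- if (roi$type == "square") (2 * roi$half_mm)^2
  else pi * roi$radius_mm^2
  if (area_vox < 0.98 * area_roi)
    stop("ROI '", roi$label, "' extends beyond the dose grid",
         call. = FALSE)
  w
}

#' Area-weighted mean dose over a region of interest
#'
#' Partial voxels are weighted by their overlap fraction with the ROI
#' (exact for square ROIs, 4 x 4 subsampled for discs), so a symmetric ROI
#' on a linear dose ramp returns exactly its center value.
#'
#' @param grid A `dose_grid`.
#' @param roi An `roi`.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(grid, roi) {
  stopifnot(inherits(grid, "dose_grid"), inherits(roi, "roi"))
  w <- .roi_weights(grid, roi)
  sum(w * grid$dose) / sum(w)
}

# Bilinear interpolation of a dose grid at scattered (x, y) mm.
.interp_dose <- function(grid, x, y) {
  px <- grid$pixel_size_mm
  cx <- (x - grid$origin_mm[1]) / px + 1
  ry <- (y - grid$origin_mm[2]) / px + 1
  n <- nrow(grid$dose); m <- ncol(grid$dose)
  c0 <- pmin(pmax(floor(cx), 1), m - 1); r0 <- pmin(pmax(floor(ry), 1),
                                                    n - 1)
  fx <- cx - c0; fy <- ry - r0
  d <- grid$dose
  d[cbind(r0, c0)] * (1 - fx) * (1 - fy) +
    d[cbind(r0, c0 + 1)] * fx * (1 - fy) +
    d[cbind(r0 + 1, c0)] * (1 - fx) * fy +
    d[cbind(r0 + 1, c0 + 1)] * fx * fy
}

#' Relative mean-dose change of an ROI displaced by a distortion field
#'
#' Computes `100 * |mean_dose(displaced roi) - mean_dose(roi)| /
#' mean_dose(roi)`, where the displaced mean samples the dose (bilinear
#' interpolation) at each ROI sample point shifted by the field evaluated
#' there. The measure is invariant to rescaling the dose grid.
#'
#' @param grid A `dose_grid`.
#' @param roi An `roi`.
#' @param field Function mapping a data.frame with columns `x`, `y`, `z`
#'   (mm) to a data.frame with `dx`, `dy` (mm); see [field_from_model()].
#' @param z_mm Slice position at which the field is evaluated.
#' @return Dose change rate in percent.
#' @export
dose_change_rate <- function(grid, roi, field, z_mm = 0) {
  stopifnot(inherits(grid, "dose_grid"), inherits(roi, "roi"),
            is.function(field))
  w <- .roi_weights(grid, roi)
  ref <- sum(w * grid$dose) / sum(w)
  if (ref == 0) stop("reference mean dose is zero", call. = FALSE)
  idx <- which(w > 0, arr.ind = TRUE)
  px <- grid$pixel_size_mm
  x <- grid$origin_mm[1] + (idx[, 2] - 1) * px
  y <- grid$origin_mm[2] + (idx[, 1] - 1) * px
  d <- field(data.frame(x = x, y = y, z = rep(z_mm, length(x))))
  disp <- sum(w[idx] * .interp_dose(grid, x + d$dx, y + d$dy)) / sum(w[idx])
  100 * abs(disp - ref) / ref
}

#' Displacement interpolant from a distortion model
#'
#' Adapter turning a [distortion_model()] plus protocol into the `field`
#' function expected by [dose_change_rate()].
#'
#' @param model A `distortion_model`.
#' @param protocol A `scan_protocol`.
#' @return Function of a points data.frame returning `dx`, `dy`, `dz`.
#' @export
field_from_model <- function(model, protocol) {
  force(model); force(protocol)
  function(points) displacement_at(model, protocol, points)
}

#' Synthetic rotationally symmetric dose grid
#'
#' Plateau at the prescription dose inside `target_radius_mm` with a
#' sigmoidal (tanh) falloff over `penumbra_mm`:
#' `D(r) = P * (1 - tanh((r - R) / (penumbra / 4))) / 2`. The center
#' receives exactly the prescription (to double precision) and dose beyond
#' one penumbra outside the target edge is below 1 percent of it.
#' Deterministic.
#'
#' @param protocol A `scan_protocol` supplying the raster, or `NULL` with
#'   explicit `matrix_px` and `fov_mm`.
#' @param prescription_gy Prescription dose (Gy), default 50.
#' @param target_radius_mm Plateau radius (mm).
#' @param penumbra_mm Falloff width (mm).
#' @param matrix_px,fov_mm Raster geometry when no protocol is given.
#' @return A `dose_grid`.
#' @export
synthetic_dose <- function(protocol = NULL, prescription_gy = 50,
                           target_radius_mm = 185, penumbra_mm = 10,
                           matrix_px = NULL, fov_mm = NULL) {
  stopifnot(prescription_gy > 0, target_radius_mm > 0, penumbra_mm > 0)
  if (!is.null(protocol)) {
    matrix_px <- protocol$matrix
    fov_mm <- protocol$fov_mm
  }
  stopifnot(!is.null(matrix_px), !is.null(fov_mm))
  px <- fov_mm / matrix_px
  ax <- (seq_len(matrix_px) - 1 - (matrix_px - 1) / 2) * px
  r <- sqrt(outer(ax^2, ax^2, "+"))
  dose <- prescription_gy * (1 - tanh((r - target_radius_mm) /
                                        (penumbra_mm / 4))) / 2
  dose_grid(dose, px, prescription_gy = prescription_gy)
}

#' Dose-impact table for a distortion field
#'
#' Evaluates [dose_change_rate()] for every ROI of the default layout on a
#' dose grid, producing the reporting-table shape (ROI, reference mean
#' dose, displaced change rate).
#'
#' @param grid A `dose_grid`.
#' @param field Displacement interpolant (see [field_from_model()]).
#' @param rois List of ROIs, default [default_rois()].
#' @param z_mm Slice position (mm).
#' @return Data frame `roi`, `reference_dose_gy`, `change_rate_pct`.
#' @export
dose_impact_table <- function(grid, field, rois = default_rois(),
                              z_mm = 0) {
  rows <- lapply(rois, function(roi)
    data.frame(roi = roi$label,
               reference_dose_gy = mean_dose(grid, roi),
               change_rate_pct = dose_change_rate(grid, roi, field, z_mm)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
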