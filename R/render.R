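# Synthetic scan renderer. The phantom is an analytic solid extruded along
# z: grid walls, diamond marker, outer rim shell and cut-chord wall in
# resin, cells filled with water. Reference (CT-role) volumes rasterize it
# directly; MR-role volumes rasterize the pre-image of the displacement
# field (inverse warp solved by fixed-point iteration on the analytic
# field), invert the water/resin contrast (T2-like) and add Rician noise.

.INT_RESIN_CT <- 1000
.INT_WATER_CT <- 60
.INT_RESIN_MR <- 60
.INT_WATER_MR <- 1000

# Material lookup in the phantom frame, vectorized over x, y, z (mm).
# Returns 0 = air/background, 1 = water, 2 = resin.
.phantom_material <- function(spec, x, y, z) {
  p <- spec$cell_pitch_mm
  w2 <- spec$wall_thickness_mm / 2
  face_r <- spec$face_diameter_mm / 2
  cut <- spec$cut_chord_offset_mm
  R <- spec$grid_inner_radius_mm
  r2 <- x^2 + y^2
  inside <- (r2 <= face_r^2) & (y >= -cut - w2) &
    (abs(z) <= spec$thickness_mm / 2)
  # distance to nearest grid line along each axis
  gx <- abs(x - p * round(x / p))
  gy <- abs(y - p * round(y / p))
  grid_line <- ((gx <= w2) | (gy <= w2)) & (r2 <= R^2) & (y >= -cut)
  chord <- abs(y + cut) <= w2 & r2 <= R^2
  rim <- r2 >= (face_r - spec$wall_thickness_mm)^2
  diamond <- (abs(x) + abs(y)) <= spec$diamond_halfwidth_mm
  resin <- inside & (grid_line | chord | rim | diamond)
  water <- inside & !resin
  ifelse(resin, 2L, ifelse(water, 1L, 0L))
}

#' Construct an image volume
#'
#' Lightweight container for a rendered or loaded volume: a 3D array
#' indexed `[row, col, slice]` where columns map to x and rows to y (both
#' increasing with the coordinate), slices are ordered foot to head, and
#' in-plane voxel centers sit at `pixel_size_mm * (index - 1) + origin_mm`.
#'
#' @param data Numeric 3D array (rows x cols x slices); a matrix is
#'   promoted to a single-slice volume.
#' @param pixel_size_mm In-plane voxel size (mm).
#' @param slice_positions_mm z position of each slice (mm, foot to head).
#' @param origin_mm Scanner-frame (x, y) of the center of voxel
#'   `[1, 1]`.
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, pixel_size_mm, slice_positions_mm,
                         origin_mm) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L, all(is.finite(data)),
            pixel_size_mm > 0,
            length(slice_positions_mm) == dim(data)[3L],
            length(origin_mm) == 2L)
  structure(list(data = data, pixel_size_mm = pixel_size_mm,
                 slice_positions_mm = as.numeric(slice_positions_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("Image volume: %d x %d x %d voxels, %.4f mm/px, ",
                     "z in [%.1f, %.1f] mm\n"),
              d[1], d[2], d[3], x$pixel_size_mm,
              min(x$slice_positions_mm), max(x$slice_positions_mm)))
  invisible(x)
}

# x (col) and y (row) voxel-center coordinates of a volume, mm.
volume_axis_x <- function(vol)
  vol$origin_mm[1] + (seq_len(dim(vol$data)[2]) - 1) * vol$pixel_size_mm
volume_axis_y <- function(vol)
  vol$origin_mm[2] + (seq_len(dim(vol$data)[1]) - 1) * vol$pixel_size_mm

# Shared rasterization core. warp_fun(x, y, z) maps scanner-frame sample
# positions to phantom-frame pre-image positions (identity for reference
# scans). Supersampling averages an s x s grid of subsamples per pixel so
# intensity approximates area coverage (anti-aliasing for sub-pixel
# localization downstream).
.render_volume <- function(spec, protocol, slice_positions, warp_fun,
                           intensities, supersample,
                           phantom_offset_mm = c(0, 0)) {
  n <- protocol$matrix
  px <- pixel_size_mm(protocol)
  if (spec$face_diameter_mm + 2 * max(abs(phantom_offset_mm)) >
      protocol$fov_mm)
    stop("phantom exceeds the field of view", call. = FALSE)
  ax <- protocol_axis_mm(protocol)
  X <- matrix(ax, n, n, byrow = TRUE)   # col -> x
  Y <- matrix(ax, n, n)                 # row -> y
  s <- as.integer(supersample)
  offs <- ((seq_len(s)) - (s + 1) / 2) / s * px
  lut <- c(intensities$air, intensities$water, intensities$resin)
  vol <- array(0, c(n, n, length(slice_positions)))
  for (si in seq_along(slice_positions)) {
    z0 <- slice_positions[si]
    acc <- matrix(0, n, n)
    for (ox in offs) for (oy in offs) {
      q <- warp_fun(X + ox, Y + oy, z0)
      m <- .phantom_material(spec, q$x - phantom_offset_mm[1],
                             q$y - phantom_offset_mm[2], q$z)
      acc <- acc + lut[m + 1L]
    }
    vol[, , si] <- acc / (s * s)
  }
  image_volume(vol, px, slice_positions, c(ax[1], ax[1]))
}

#' Render an undistorted reference (CT-role) volume
#'
#' Deterministic, noiseless rasterization of the phantom with CT-like
#' contrast (resin bright, water dark). The reference volume plays the role
#' of the gold-standard geometry.
#'
#' @param spec A `phantom_spec`.
#' @param protocol A `scan_protocol`.
#' @param slice_positions_mm Slice z positions (mm); default: the
#'   protocol's `n_slices` centered on the phantom mid-plane. Pass `0` for
#'   the central transverse slice only.
#' @param phantom_offset_mm In-plane (x, y) offset of the phantom center
#'   relative to the isocenter (mm); used for setup-translation studies.
#' @param supersample Subsamples per pixel side for anti-aliasing
#'   (default 4).
#' @return An `image_volume`.
#' @export
render_reference <- function(spec, protocol, slice_positions_mm = 0,
                             phantom_offset_mm = c(0, 0), supersample = 4) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(protocol, "scan_protocol"))
  .render_volume(spec, protocol, slice_positions_mm,
                 function(x, y, z) list(x = x, y = y, z = z),
                 list(air = 0, water = .INT_WATER_CT,
                      resin = .INT_RESIN_CT),
                 supersample, phantom_offset_mm)
}

#' Render a distorted MR-role volume
#'
#' Applies the distortion model as an inverse warp: each output sample
#' position `p` shows the material at the pre-image `q` solving
#' `q + d(q) = p`, found by fixed-point iteration `q <- p - d(q)` (the
#' smooth sub-voxel-scale fields used here converge in a few iterations).
#' Contrast is T2-like (water bright, resin dark) and Rician noise of the
#' requested signal-to-noise ratio (water signal / Gaussian sigma) is added
#' using the model's seed, so identical inputs give identical volumes.
#'
#' @inheritParams render_reference
#' @param model A `distortion_model`.
#' @param snr Signal-to-noise ratio; `Inf` for a noiseless rendering.
#' @param max_displacement_warn Warn if the maximum displacement sampled
#'   exceeds this magnitude (mm): the fixed-point inversion assumes a
#'   sub-cell-scale, invertible field.
#' @return An `image_volume`.
#' @export
render_mr <- function(spec, protocol, model, snr = 30,
                      slice_positions_mm = 0, phantom_offset_mm = c(0, 0),
                      supersample = 4, max_displacement_warn = 8) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(protocol, "scan_protocol"),
            inherits(model, "distortion_model"), snr > 0)
  dmax_seen <- 0
  support_r2 <- (spec$face_diameter_mm / 2 + 10)^2
  warp <- function(x, y, z) {
    qx <- x; qy <- y; qz <- z
    for (it in 1:3) {
      d <- .displacement_xyz(model, protocol, qx, qy, qz)
      qx <- x - d$dx; qy <- y - d$dy; qz <- z - d$dz
    }
    # judge invertibility where it matters: over the phantom support, not
    # at FOV corners where a polynomial field extrapolates freely
    in_sup <- x^2 + y^2 <= support_r2
    if (any(in_sup))
      dmax_seen <<- max(dmax_seen,
                        sqrt(max((d$dx^2 + d$dy^2 + d$dz^2)[in_sup])))
    list(x = qx, y = qy, z = qz)
  }
  vol <- .render_volume(spec, protocol, slice_positions_mm, warp,
                        list(air = 0, water = .INT_WATER_MR,
                             resin = .INT_RESIN_MR),
                        supersample, phantom_offset_mm)
  if (dmax_seen > max_displacement_warn)
    warning(sprintf(paste0("maximum sampled displacement %.2f mm exceeds ",
                           "%g mm; inverse warp may be inaccurate"),
                    dmax_seen, max_displacement_warn))
  if (is.finite(snr)) {
    sigma <- .INT_WATER_MR / snr
    vol$data <- .with_seed(model$seed, {
      nv <- length(vol$data)
      sqrt((vol$data + stats::rnorm(nv, 0, sigma))^2 +
             stats::rnorm(nv, 0, sigma)^2)
    })
  }
  vol
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read an image volume as NIfTI
#'
#' @param vol An `image_volume`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   an `image_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  dz <- if (length(vol$slice_positions_mm) > 1L)
    diff(vol$slice_positions_mm)[1] else 1
  # store as x, y, z with x fastest: transpose rows/cols
  arr <- aperm(vol$data, c(2L, 1L, 3L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vol$pixel_size_mm, vol$pixel_size_mm, dz)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param origin_mm,slice_positions_mm Geometry to attach on reading
#'   (NIfTI stores spacing; the scanner-frame origin convention of this
#'   package is re-derived from the matrix size when omitted).
#' @export
read_volume <- function(path, origin_mm = NULL, slice_positions_mm = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  pd <- RNifti::pixdim(img)
  px <- pd[1]
  arr <- aperm(arr, c(2L, 1L, 3L))
  n <- dim(arr)[1:2]
  if (is.null(origin_mm)) origin_mm <- -(n[2:1] - 1) / 2 * px
  if (is.null(slice_positions_mm)) {
    dz <- if (length(pd) >= 3) pd[3] else 1
    ns <- dim(arr)[3]
    slice_positions_mm <- (seq_len(ns) - 1 - (ns - 1) / 2) * dz
  }
  image_volume(arr, px, slice_positions_mm, origin_mm)
}
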