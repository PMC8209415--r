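# Scanner protocol presets. The three presets mirror the acquisition
# parameters of the systems compared in the study conditions this package
# simulates: an Elekta Unity MR-Linac (3D T2 series, thin contiguous
# slices), a GE Signa HDe 1.5T and a GE Discovery 750 3.0T. Defaults for
# n_slices cover (most of) the 220 mm phantom thickness, centered on the
# phantom mid-plane.

.protocol_presets <- list(
  unity = list(name = "unity", fov_mm = 537.6, matrix = 1008L,
               pixel_bandwidth_hz_per_px = 1033,
               slice_thickness_mm = 1.6, n_slices = 120L,
               freq_encode_axis = "x", acquisition_3d = TRUE),
  ge_hde = list(name = "ge_hde", fov_mm = 480, matrix = 512L,
                pixel_bandwidth_hz_per_px = 195.31,
                slice_thickness_mm = 5, n_slices = 44L,
                freq_encode_axis = "x", acquisition_3d = FALSE),
  ge_750 = list(name = "ge_750", fov_mm = 500, matrix = 512L,
                pixel_bandwidth_hz_per_px = 195.31,
                slice_thickness_mm = 3, n_slices = 60L,
                freq_encode_axis = "x", acquisition_3d = FALSE)
)

#' Construct a scan protocol
#'
#' A scan protocol describes one scanner acquisition: square field of view,
#' acquisition matrix, pixel bandwidth (Hz per pixel, controlling the
#' off-resonance displacement along the frequency-encode axis), slice
#' thickness/spacing and slice count. `pixel_size_mm = fov_mm / matrix`.
#'
#' @param name Protocol label.
#' @param fov_mm Square field of view (mm).
#' @param matrix Pixels per side.
#' @param pixel_bandwidth_hz_per_px Pixel bandwidth (Hz/px), positive.
#' @param slice_thickness_mm Slice thickness = slice spacing (mm).
#' @param n_slices Default number of slices, centered on the phantom
#'   mid-plane.
#' @param freq_encode_axis `"x"` or `"y"`: readout direction along which B0
#'   off-resonance displaces image content.
#' @param acquisition_3d Logical marker for 3D (contiguous thin-slice)
#'   series.
#' @return A `scan_protocol` object.
#' @export
scan_protocol <- function(name, fov_mm, matrix, pixel_bandwidth_hz_per_px,
                          slice_thickness_mm, n_slices = 1L,
                          freq_encode_axis = c("x", "y"),
                          acquisition_3d = FALSE) {
  freq_encode_axis <- match.arg(freq_encode_axis)
  stopifnot(fov_mm > 0, matrix >= 2, pixel_bandwidth_hz_per_px > 0,
            slice_thickness_mm > 0, n_slices >= 1)
  structure(list(name = as.character(name), fov_mm = fov_mm,
                 matrix = as.integer(matrix),
                 pixel_bandwidth_hz_per_px = pixel_bandwidth_hz_per_px,
                 slice_thickness_mm = slice_thickness_mm,
                 n_slices = as.integer(n_slices),
                 freq_encode_axis = freq_encode_axis,
                 acquisition_3d = isTRUE(acquisition_3d)),
            class = "scan_protocol")
}

#' Scanner protocol presets
#'
#' Returns the acquisition parameters of one of the three built-in
#' scanners: `"unity"` (537.6 mm FOV, 1008^2 matrix, 1033 Hz/px, 3D series
#' rendered as contiguous 1.6 mm slices), `"ge_hde"` (480 mm FOV, 512^2,
#' 195.31 Hz/px, 5 mm slices) or `"ge_750"` (500 mm FOV, 512^2,
#' 195.31 Hz/px, 3 mm slices).
#'
#' @param name One of `"unity"`, `"ge_hde"`, `"ge_750"`.
#' @return A `scan_protocol`.
#' @examples
#' protocol_preset("unity")$pixel_bandwidth_hz_per_px  # 1033
#' @export
protocol_preset <- function(name = c("unity", "ge_hde", "ge_750")) {
  name <- match.arg(name)
  do.call(scan_protocol, .protocol_presets[[name]])
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(paste0("Scan protocol '%s': FOV %g mm, matrix %d ",
                     "(%.4f mm/px), %g Hz/px, slices %d x %g mm, ",
                     "freq-encode %s%s\n"),
              x$name, x$fov_mm, x$matrix, pixel_size_mm(x),
              x$pixel_bandwidth_hz_per_px, x$n_slices,
              x$slice_thickness_mm, x$freq_encode_axis,
              if (x$acquisition_3d) " (3D series)" else ""))
  invisible(x)
}

#' Pixel size of a protocol
#'
#' @param protocol A `scan_protocol`.
#' @return In-plane pixel size `fov_mm / matrix` in mm.
#' @export
pixel_size_mm <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  protocol$fov_mm / protocol$matrix
}

# In-plane voxel-center coordinates (mm, scanner frame). The isocenter sits
# on the central voxel for odd matrices and between voxels for even ones:
# coordinate of index i (1-based) is (i - 1 - (matrix - 1)/2) * pixel.
protocol_axis_mm <- function(protocol) {
  px <- pixel_size_mm(protocol)
  (seq_len(protocol$matrix) - 1 - (protocol$matrix - 1) / 2) * px
}

# Default slice positions: n slices centered on the phantom mid-plane,
# foot (most negative z) first.
protocol_slice_positions <- function(protocol, n_slices = NULL) {
  n <- if (is.null(n_slices)) protocol$n_slices else as.integer(n_slices)
  dz <- protocol$slice_thickness_mm
  (seq_len(n) - 1 - (n - 1) / 2) * dz
}
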