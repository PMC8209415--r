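# Parametric displacement-field model. Total displacement at a point is
# the gradient-nonlinearity (GNL) term, a smooth polynomial vector field
# vanishing at the isocenter, plus the B0 off-resonance term
# (dB0 / pixel_bandwidth) * pixel_size along the frequency-encode axis.
# Lower pixel bandwidth therefore enlarges the B0 component in exact
# inverse proportion.

#' Construct a parametric distortion model
#'
#' The model combines a gradient-nonlinearity (GNL) displacement field,
#' given as one sparse trivariate polynomial per output axis (monomial
#' tables with columns `i`, `j`, `k`, `c`: coefficient `c` on
#' `x^i y^j z^k`, mm in, mm out), with a scalar B0 off-resonance map in Hz
#' (same monomial form). Both are required to vanish at the isocenter
#' unless `enforce_isocenter = FALSE` (distortion is smallest at the
#' magnet center, which is why center-point registration is meaningful).
#'
#' @param gnl List with polynomial components `x`, `y`, `z` (any may be
#'   omitted), e.g. from [radial_gnl()]; `NULL` for no GNL term.
#' @param b0 Scalar off-resonance polynomial (Hz), e.g. from
#'   [parabolic_b0()]; `NULL` for a homogeneous field.
#' @param seed Integer seed controlling the reproducible noise of
#'   [render_mr()].
#' @param enforce_isocenter Require zero displacement and zero
#'   off-resonance at (0,0,0). Disable only for deliberate rigid-shift
#'   constructions.
#' @return A `distortion_model` object.
#' @export
distortion_model <- function(gnl = NULL, b0 = NULL, seed = 1L,
                             enforce_isocenter = TRUE) {
  if (is.null(gnl)) gnl <- list()
  if (!is.list(gnl)) stop("gnl must be a list of axis polynomials",
                          call. = FALSE)
  bad <- setdiff(names(gnl), c("x", "y", "z"))
  if (length(bad)) stop("unknown gnl axis: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  gnl <- lapply(gnl, function(p) poly_check(p, "gnl component"))
  for (ax in c("x", "y", "z")) if (is.null(gnl[[ax]])) gnl[[ax]] <- poly_zero()
  if (is.null(b0)) b0 <- poly_zero()
  poly_check(b0, "b0 map")
  if (enforce_isocenter) {
    if (any(vapply(gnl, poly_has_constant, logical(1))))
      stop("GNL field must vanish at the isocenter ",
           "(no constant monomials); see enforce_isocenter", call. = FALSE)
    if (poly_has_constant(b0))
      stop("B0 map must vanish at the isocenter; see enforce_isocenter",
           call. = FALSE)
  }
  structure(list(gnl = gnl[c("x", "y", "z")], b0 = b0,
                 seed = as.integer(seed)),
            class = "distortion_model")
}

#' @export
print.distortion_model <- function(x, ...) {
  nmono <- vapply(x$gnl, nrow, integer(1))
  cat(sprintf(paste0("Distortion model: GNL monomials x/y/z = %d/%d/%d, ",
                     "B0 monomials = %d, seed = %d\n"),
              nmono[1], nmono[2], nmono[3], nrow(x$b0), x$seed))
  invisible(x)
}

#' Odd-order radial gradient-nonlinearity field
#'
#' Builds a radially directed displacement field whose magnitude grows as a
#' mixture of cubic and quintic terms in the distance from the isocenter:
#' `|d|(r) = dmax * ((1 - w5) (r/r_ref)^3 + w5 (r/r_ref)^5)`, so the
#' maximum in-lattice displacement at `r = r_ref` equals `dmax_mm` exactly
#' and the field vanishes (with zero gradient) at the center, emulating how
#' gradient nonlinearity grows from the isocenter outwards.
#'
#' @param dmax_mm Displacement magnitude at `r_ref_mm` (mm).
#' @param r_ref_mm Reference radius, default 170 mm (the lattice edge).
#' @param w5 Weight of the quintic term in `[0, 1]`.
#' @return List of axis polynomials suitable for [distortion_model()].
#' @export
radial_gnl <- function(dmax_mm, r_ref_mm = 170, w5 = 0.25) {
  stopifnot(is.numeric(dmax_mm), r_ref_mm > 0, w5 >= 0, w5 <= 1)
  r2 <- poly_new(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L), c(1, 1, 1))
  r4 <- poly_mul(r2, r2)
  # d_axis = axis_coord * (c3 * r^2 + c5 * r^4); |d| = r * (...) as stated.
  radial <- poly_add(poly_scale(r2, dmax_mm * (1 - w5) / r_ref_mm^3),
                     poly_scale(r4, dmax_mm * w5 / r_ref_mm^5))
  list(x = poly_mul(poly_new(1L, 0L, 0L, 1), radial),
       y = poly_mul(poly_new(0L, 1L, 0L, 1), radial),
       z = poly_mul(poly_new(0L, 0L, 1L, 1), radial))
}

#' Parabolic B0 off-resonance map
#'
#' `dB0(x, y, z) = amp_hz * r^2 / r_ref^2` (Hz): zero at the isocenter,
#' reaching `amp_hz` at radius `r_ref_mm`. Illustrative of a smooth shim
#' residual; real scanner B0 maps are machine-specific.
#'
#' @param amp_hz Off-resonance at `r_ref_mm`, in Hz.
#' @param r_ref_mm Reference radius (mm).
#' @return A monomial table usable as the `b0` argument of
#'   [distortion_model()].
#' @export
parabolic_b0 <- function(amp_hz, r_ref_mm = 170) {
  stopifnot(is.numeric(amp_hz), r_ref_mm > 0)
  poly_scale(poly_new(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L),
                      c(1, 1, 1)),
             amp_hz / r_ref_mm^2)
}

#' Distortion-field presets scaled to the three scanner magnitudes
#'
#' Convenience constructors of [distortion_model()] objects with a radial
#' GNL field whose maximum displacement at r = 170 mm is 1 mm
#' (`"unity_like"`), 1.5 mm (`"ge_hde_like"`) or 3 mm (`"ge_750_like"`),
#' mimicking the relative distortion magnitudes of the three systems. The
#' `"zero"` preset has no distortion at all. B0 defaults to zero
#' (homogeneous field); pass `b0_amp_hz` to add a parabolic off-resonance
#' bowl.
#'
#' @param name Preset name.
#' @param seed Noise seed stored in the model.
#' @param b0_amp_hz Optional parabolic B0 amplitude at 170 mm (Hz).
#' @return A `distortion_model`.
#' @export
field_preset <- function(name = c("unity_like", "ge_hde_like",
                                  "ge_750_like", "zero"),
                         seed = 1L, b0_amp_hz = 0) {
  name <- match.arg(name)
  dmax <- switch(name, unity_like = 1, ge_hde_like = 1.5,
                 ge_750_like = 3, zero = 0)
  gnl <- if (dmax > 0) radial_gnl(dmax) else NULL
  b0 <- if (b0_amp_hz != 0) parabolic_b0(b0_amp_hz) else NULL
  distortion_model(gnl = gnl, b0 = b0, seed = seed)
}

#' Evaluate the displacement field at points
#'
#' Total displacement at a point is the GNL polynomial evaluated there plus
#' the B0 term `(dB0 / pixel_bandwidth) * pixel_size` directed along the
#' protocol's frequency-encode axis. The B0 component scales exactly as
#' 1/bandwidth: halving the pixel bandwidth doubles it.
#'
#' @param model A `distortion_model`.
#' @param protocol A `scan_protocol` (supplies pixel bandwidth, pixel size
#'   and the frequency-encode axis).
#' @param points Data frame or matrix with columns `x`, `y`, `z` (mm); a
#'   length-3 vector is accepted for a single point.
#' @return Data frame with columns `dx`, `dy`, `dz` (mm).
#' @export
displacement_at <- function(model, protocol, points) {
  stopifnot(inherits(model, "distortion_model"),
            inherits(protocol, "scan_protocol"))
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 3L)
    points <- data.frame(x = points[1], y = points[2], z = points[3])
  points <- as.data.frame(points)
  if (!all(c("x", "y", "z") %in% names(points)))
    stop("points must have columns x, y, z", call. = FALSE)
  d <- .displacement_xyz(model, protocol, points$x, points$y, points$z)
  data.frame(dx = d$dx, dy = d$dy, dz = d$dz)
}

# Vectorized core shared with the renderer (plain numeric vectors in/out).
.displacement_xyz <- function(model, protocol, x, y, z) {
  dx <- poly_eval(model$gnl$x, x, y, z)
  dy <- poly_eval(model$gnl$y, x, y, z)
  dz <- poly_eval(model$gnl$z, x, y, z)
  if (nrow(model$b0) > 0L) {
    shift <- poly_eval(model$b0, x, y, z) /
      protocol$pixel_bandwidth_hz_per_px * pixel_size_mm(protocol)
    if (protocol$freq_encode_axis == "x") dx <- dx + shift
    else dy <- dy + shift
  }
  list(dx = dx, dy = dy, dz = dz)
}

#' Ground-truth displacements at every lattice node
#'
#' Evaluates the exact displacement field at every node of the lattice for
#' each requested slice position. This table is the recovery oracle against
#' which the detection pipeline is validated.
#'
#' @param model A `distortion_model`.
#' @param protocol A `scan_protocol`.
#' @param lattice A `node_lattice`.
#' @param slice_z Numeric vector of slice positions (mm), default 0 (the
#'   central transverse plane).
#' @return Data frame with columns `node_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `dx_mm`, `dy_mm`, `dz_mm`.
#' @export
true_displacements <- function(model, protocol, lattice, slice_z = 0) {
  stopifnot(inherits(lattice, "node_lattice"))
  out <- do.call(rbind, lapply(slice_z, function(z) {
    n <- lattice$nodes
    d <- .displacement_xyz(model, protocol, n$x_mm, n$y_mm,
                           rep(z, nrow(n)))
    data.frame(node_id = n$node_id, x_mm = n$x_mm, y_mm = n$y_mm,
               z_mm = z, dx_mm = d$dx, dy_mm = d$dy, dz_mm = d$dz)
  }))
  rownames(out) <- NULL
  out
}
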