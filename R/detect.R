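# Automatic control-point extraction. Grid intersections are located by
# normalized cross-correlation (NCC) with a cross-shaped template (arm
# length half a cell pitch), non-maximum suppression, and sub-pixel
# refinement by intensity centroids across each grid wall. The absolute
# NCC value is used throughout, which makes detection agnostic to the
# CT-like (resin bright) versus T2-like (water bright) contrast polarity.

# Integral-image box sums: sum of img over the (2a+1) x (2b+1) window
# centered at each pixel; border pixels whose window exits the image get NA.
.box_sum <- function(img, a, b) {
  n <- nrow(img); m <- ncol(img)
  ii <- rbind(0, apply(img, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  out <- matrix(NA_real_, n, m)
  r <- (a + 1):(n - a); cl <- (b + 1):(m - b)
  out[r, cl] <- ii[r + a + 1, cl + b + 1] - ii[r - a, cl + b + 1] -
    ii[r + a + 1, cl - b] + ii[r - a, cl - b]
  out
}

# Normalized cross-correlation of a zero-mean template with an image.
# Returns a matrix aligned with img (template centered on each pixel);
# border band is 0. Template must have odd dimensions.
.ncc <- function(img, tmpl) {
  stopifnot(nrow(tmpl) %% 2 == 1, ncol(tmpl) %% 2 == 1)
  t0 <- tmpl - mean(tmpl)
  nt <- sqrt(sum(t0^2))
  if (nt == 0) stop("degenerate template", call. = FALSE)
  num <- EBImage::filter2(img, t0, boundary = 0)
  a <- (nrow(tmpl) - 1) / 2; b <- (ncol(tmpl) - 1) / 2
  N <- length(tmpl)
  s1 <- .box_sum(img, a, b)
  s2 <- .box_sum(img^2, a, b)
  v <- pmax(s2 - s1^2 / N, 0)
  den <- sqrt(v) * nt
  out <- ifelse(is.na(den) | den < 1e-8 * N, 0, num / den)
  out[!is.finite(out)] <- 0
  out
}

# Fuzzy (anti-aliased) strip membership: 1 on the strip of half-width hw,
# linear rolloff over one pixel.
.soft_strip <- function(d, hw) pmin(pmax(hw + 0.5 - abs(d), 0), 1)

# Cross template in pixel units for a given protocol/spec.
.cross_template <- function(spec, px) {
  half <- max(3L, as.integer(round(spec$cell_pitch_mm / 2 / px)) - 1L)
  hw <- spec$wall_thickness_mm / 2 / px
  u <- seq(-half, half)
  X <- matrix(u, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  Y <- matrix(u, 2 * half + 1, 2 * half + 1)
  pmax(.soft_strip(X, hw), .soft_strip(Y, hw))
}

# Diamond template (|x| + |y| <= halfwidth), fuzzy edge.
.diamond_template <- function(spec, px) {
  half <- as.integer(ceiling((spec$diamond_halfwidth_mm +
                                spec$cell_pitch_mm / 2) / px))
  u <- seq(-half, half)
  X <- matrix(u, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  Y <- matrix(u, 2 * half + 1, 2 * half + 1)
  pmin(pmax(spec$diamond_halfwidth_mm / px + 0.5 - (abs(X) + abs(Y)), 0), 1)
}

.detect_error <- function(msg, class) {
  stop(structure(class = c(class, "mrgridqa_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Iterated fuzzy-window centroid of a ridge in profile `p` (baseline
# subtracted, polarity corrected, negatives clipped). The window has
# fractional-coverage edge weights and is re-centered on the running
# estimate, so at convergence it is symmetric around the reported
# position and window clipping adds no bias. Returns the fractional index
# of the ridge center, or NA.
.ridge_centroid <- function(p, m0, k) {
  est <- as.numeric(m0)
  for (it in 1:4) {
    i <- seq_along(p)
    w <- pmin(pmax(k + 0.5 - abs(i - est), 0), 1) * p
    if (sum(w) <= 0) return(NA_real_)
    new <- sum(w * i) / sum(w)
    if (abs(new - est) < 1e-4) { est <- new; break }
    est <- new
  }
  est
}

# Subtract a linear baseline fit through the two flank regions at
# distance (k+1)..(k+f) from the ridge center; removes constant and
# step/ramp backgrounds (e.g. a wall present on one side only).
.deflank <- function(p, m0, k, f = 3L) {
  i <- seq_along(p)
  lf <- i >= m0 - k - f & i <= m0 - k - 1
  rf <- i >= m0 + k + 1 & i <= m0 + k + f
  if (!any(lf) || !any(rf)) return(p - stats::median(p))
  xl <- mean(i[lf]); yl <- mean(p[lf])
  xr <- mean(i[rf]); yr <- mean(p[rf])
  slope <- (yr - yl) / (xr - xl)
  p - (yl + slope * (i - xl))
}

# Sub-pixel refinement of a grid crossing at integer pixel (r0, c0). The
# x coordinate is the centroid of the vertical wall's column profile,
# computed from rows that EXCLUDE the horizontal-wall band (so the
# perpendicular wall, or its absence at arm-end crossings, cannot bias
# the profile), and symmetrically for y. Returns c(row, col) with
# sub-pixel precision, or NULL when the window exits the image or the
# ridge is degenerate.
.refine_cross <- function(img, r0, c0, pitch_px, wall_px, upsample = 1L) {
  wr <- max(3L, as.integer(round(0.35 * pitch_px)))
  ex <- as.integer(ceiling(wall_px / 2)) + 1L   # excluded central band
  k <- as.integer(ceiling(wall_px / 2)) + 1L    # ridge half-window
  wc <- k + 7L                                   # profile half-width
  n <- nrow(img); m <- ncol(img)
  band <- function(w) { s <- seq(-w, w); s[abs(s) > ex] }
  sub_axis <- function(prof) {
    mid <- (length(prof) + 1L) %/% 2L
    ctr <- seq(mid - 3L, mid + 3L)   # ridge search range around the window
    p0 <- prof - stats::median(prof)
    if (sum(p0[ctr]) < 0) p0 <- -p0
    m0 <- ctr[which.max(p0[ctr])]
    # ridge validity: the two flank levels must agree to within the ridge
    # amplitude, otherwise the profile is an edge (e.g. the water/air
    # interface at the cut chord on T2 contrast), whose centroid does not
    # locate a wall - reject the measurement
    i <- seq_along(prof)
    lf <- i >= m0 - k - 3L & i <= m0 - k - 1L
    rf <- i >= m0 + k + 1L & i <= m0 + k + 3L
    if (!any(lf) || !any(rf)) return(NA_real_)
    yl <- mean(prof[lf]); yr <- mean(prof[rf])
    amp <- abs(prof[m0] - (yl + yr) / 2)
    if (amp <= 0 || abs(yl - yr) >= amp) return(NA_real_)
    p <- .deflank(prof, m0, k)
    if (sum(p[(m0 - 1L):(m0 + 1L)]) < 0) p <- -p
    p[p < 0] <- 0
    est <- .ridge_centroid(p, m0, k)
    if (is.na(est) || abs(est - m0) > 2) return(NA_real_)
    est - mid
  }
  one_pass <- function(r0, c0) {
    if (r0 - max(wr, wc) < 1 || r0 + max(wr, wc) > n ||
        c0 - max(wr, wc) < 1 || c0 + max(wr, wc) > m)
      return(NULL)
    dx <- sub_axis(colMeans(img[r0 + band(wr), (c0 - wc):(c0 + wc),
                                drop = FALSE]))
    dy <- sub_axis(rowMeans(img[(r0 - wc):(r0 + wc), c0 + band(wr),
                                drop = FALSE]))
    if (is.na(dx) || is.na(dy)) return(NULL)
    c(r0 + dy, c0 + dx)
  }
  est <- one_pass(r0, c0)
  if (is.null(est)) return(NULL)
  # when the seed peak was off-center (e.g. arm-end corners under strong
  # distortion), re-center so the second pass measures an unclipped,
  # symmetric profile
  if (max(abs(est - c(r0, c0))) > 1.2) {
    est <- one_pass(as.integer(round(est[1])), as.integer(round(est[2])))
    if (is.null(est)) return(NULL)
  }
  est
}


#' Locate the central diamond marker in a transverse slice
#'
#' Finds the phantom's solid diamond positioning marker by normalized
#' cross-correlation with a diamond template (absolute response, so both
#' CT-like and T2-like contrast work) and refines its position to sub-pixel
#' precision with an intensity centroid. The marker center defines the
#' phantom center used for center-point registration.
#'
#' @param slice Numeric matrix (one transverse slice, rows = y, cols = x)
#'   or an `image_volume` (its first slice is used unless `slice_index`
#'   says otherwise).
#' @param spec A `phantom_spec`.
#' @param pixel_size_mm Pixel size; taken from the volume when `slice` is
#'   an `image_volume`.
#' @param origin_mm Scanner-frame coordinates of pixel `[1, 1]`; taken
#'   from the volume when available.
#' @param slice_index Which slice of a volume to use.
#' @param min_response Minimum absolute NCC response; below it a
#'   "center not found" error (condition class `mrgridqa_center_not_found`)
#'   is signalled.
#' @return A one-row data.frame: `x_mm`, `y_mm`, `response`.
#' @export
find_center_marker <- function(slice, spec, pixel_size_mm = NULL,
                               origin_mm = NULL, slice_index = 1L,
                               min_response = 0.35) {
  g <- .slice_geometry(slice, pixel_size_mm, origin_mm, slice_index)
  tmpl <- .diamond_template(spec, g$px)
  resp <- abs(.ncc(g$img, tmpl))
  pk <- which(resp == max(resp), arr.ind = TRUE)[1, ]
  if (max(resp) < min_response)
    .detect_error("center not found: no diamond-like response above threshold",
                  "mrgridqa_center_not_found")
  # iterated fuzzy-window centroid of the polarity-corrected marker blob:
  # the window is re-centered on the running estimate with fractional
  # edge weights, so clipping is symmetric around the converged position
  # window must cover the marker but stay clear of the first grid line at
  # one cell pitch (inner wall edge at pitch - wall/2), else the line's
  # mass destabilizes the centroid
  W_mm <- min(spec$diamond_halfwidth_mm + 1,
              spec$cell_pitch_mm - spec$wall_thickness_mm / 2 - 1.5)
  W <- W_mm / g$px
  r0 <- pk[1]; c0 <- pk[2]
  n <- nrow(g$img); m <- ncol(g$img)
  Wi <- as.integer(ceiling(W)) + 1L
  rr <- max(1, r0 - Wi - 2L):min(n, r0 + Wi + 2L)
  cc <- max(1, c0 - Wi - 2L):min(m, c0 + Wi + 2L)
  # baseline: the cell-fill (water) intensity dominates the patch area,
  # so the patch median is a contrast-agnostic background estimate
  patch <- g$img[rr, cc]
  patch <- patch - stats::median(patch)
  ctr_val <- patch[which.min(abs(rr - r0)), which.min(abs(cc - c0))]
  if (length(ctr_val) && ctr_val < 0) patch <- -patch
  patch[patch < 0] <- 0
  est <- c(r0, c0)
  for (it in 1:5) {
    wr <- pmin(pmax(W + 0.5 - abs(rr - est[1]), 0), 1)
    wc <- pmin(pmax(W + 0.5 - abs(cc - est[2]), 0), 1)
    wmat <- outer(wr, wc) * patch
    if (sum(wmat) <= 0) break
    new <- c(sum(rowSums(wmat) * rr), sum(colSums(wmat) * cc)) / sum(wmat)
    new <- pmin(pmax(new, c(r0, c0) - 2), c(r0, c0) + 2)
    if (max(abs(new - est)) < 1e-4) { est <- new; break }
    est <- new
  }
  data.frame(x_mm = g$origin[1] + (est[2] - 1) * g$px,
             y_mm = g$origin[2] + (est[1] - 1) * g$px,
             response = max(resp))
}

# Normalize slice input to (img matrix, px, origin).
.slice_geometry <- function(slice, pixel_size_mm, origin_mm, slice_index) {
  if (inherits(slice, "image_volume")) {
    img <- slice$data[, , slice_index]
    px <- slice$pixel_size_mm
    org <- slice$origin_mm
  } else {
    img <- slice
    if (is.null(pixel_size_mm))
      stop("pixel_size_mm required for a bare matrix slice", call. = FALSE)
    px <- pixel_size_mm
    org <- if (is.null(origin_mm)) -(dim(img)[2:1] - 1) / 2 * px
    else origin_mm
  }
  list(img = img, px = px, origin = org)
}

#' Detect grid intersections in a transverse slice
#'
#' Computes the absolute normalized cross-correlation of the slice with a
#' cross template (arm length half a cell pitch), keeps local maxima above
#' a response threshold with non-maximum suppression within half a cell
#' pitch, and refines every peak to sub-pixel precision by wall-profile
#' centroids. Detections falling inside the central diamond are replaced
#' by the marker position when `center` is supplied. Peaks whose
#' refinement window exits the image (partially visible edge crossings)
#' are dropped.
#'
#' @inheritParams find_center_marker
#' @param protocol Optional `scan_protocol` (only used for the pixel size
#'   when `slice` is a bare matrix).
#' @param upsample Sub-pixel refinement factor (>= 1) retained for
#'   compatibility with high-zoom workflows; the centroid refinement is
#'   already sub-pixel so values above 1 change nothing measurable.
#' @param min_response Minimum absolute NCC peak response.
#' @param center Optional center marker (from [find_center_marker()]).
#' @return Data frame of detections: `x_mm`, `y_mm`, `response`,
#'   `slice_index`. Fewer than 9 detections signal a "grid not detected"
#'   error (condition class `mrgridqa_grid_not_found`).
#' @export
detect_nodes <- function(slice, spec, protocol = NULL, upsample = 1L,
                         pixel_size_mm = NULL, origin_mm = NULL,
                         slice_index = 1L, min_response = 0.3,
                         center = NULL) {
  stopifnot(upsample >= 1)
  if (is.null(pixel_size_mm) && !is.null(protocol))
    pixel_size_mm <- pixel_size_mm(protocol)
  g <- .slice_geometry(slice, pixel_size_mm, origin_mm, slice_index)
  pitch_px <- spec$cell_pitch_mm / g$px
  wall_px <- spec$wall_thickness_mm / g$px
  tmpl <- .cross_template(spec, g$px)
  resp <- abs(.ncc(g$img, tmpl))
  thr <- max(min_response, 0.5 * max(resp))
  cand <- which(resp >= thr)
  if (length(cand) == 0L)
    .detect_error("grid not detected: no crossing response above threshold",
                  "mrgridqa_grid_not_found")
  ord <- cand[order(resp[cand], decreasing = TRUE)]
  rc <- cbind((ord - 1L) %% nrow(resp) + 1L,
              (ord - 1L) %/% nrow(resp) + 1L)
  sup2 <- (pitch_px / 2)^2
  acc_r <- numeric(0); acc_c <- numeric(0); acc_v <- numeric(0)
  for (t in seq_len(nrow(rc))) {
    r <- rc[t, 1]; cc <- rc[t, 2]
    if (length(acc_r) == 0L ||
        min((acc_r - r)^2 + (acc_c - cc)^2) > sup2) {
      acc_r <- c(acc_r, r); acc_c <- c(acc_c, cc)
      acc_v <- c(acc_v, resp[r, cc])
    }
  }
  out_x <- numeric(0); out_y <- numeric(0); out_v <- numeric(0)
  dia_px <- (spec$diamond_halfwidth_mm + spec$wall_thickness_mm) / g$px
  ctr_px <- if (!is.null(center))
    c((center$y_mm - g$origin[2]) / g$px + 1,
      (center$x_mm - g$origin[1]) / g$px + 1) else NULL
  for (t in seq_along(acc_r)) {
    if (!is.null(ctr_px) &&
        (acc_r[t] - ctr_px[1])^2 + (acc_c[t] - ctr_px[2])^2 <= dia_px^2) {
      out_x <- c(out_x, center$x_mm); out_y <- c(out_y, center$y_mm)
      out_v <- c(out_v, acc_v[t])
      next
    }
    rcx <- .refine_cross(g$img, acc_r[t], acc_c[t], pitch_px, wall_px,
                         upsample)
    if (is.null(rcx)) next
    out_x <- c(out_x, g$origin[1] + (rcx[2] - 1) * g$px)
    out_y <- c(out_y, g$origin[2] + (rcx[1] - 1) * g$px)
    out_v <- c(out_v, acc_v[t])
  }
  if (!is.null(center) &&
      !any((out_x - center$x_mm)^2 + (out_y - center$y_mm)^2 <=
             dia_px^2 * g$px^2)) {
    # the solid marker has no grid crossing of its own: the marker center
    # stands in for the central node
    out_x <- c(out_x, center$x_mm)
    out_y <- c(out_y, center$y_mm)
    out_v <- c(out_v, center$response)
  }
  if (length(out_x) < 9L)
    .detect_error(sprintf("grid not detected: only %d crossings found",
                          length(out_x)), "mrgridqa_grid_not_found")
  data.frame(x_mm = out_x, y_mm = out_y, response = out_v,
             slice_index = slice_index)
}

#' Match detected points to the reference lattice
#'
#' Registers the detected point cloud to the reference lattice by
#' center-point translation (the detected marker center is moved to the
#' lattice origin; no rotation or scaling, mirroring the registration
#' depth of the manual procedure) and pairs each lattice node with the
#' nearest detected point within a gate of half a cell pitch. Matching is
#' one-to-one, greedy by ascending pair distance.
#'
#' @param detected Data frame from [detect_nodes()].
#' @param lattice A `node_lattice`.
#' @param center Center marker data.frame from [find_center_marker()]; its
#'   coordinates are subtracted from all detections.
#' @param gate_mm Assignment gate; default half a cell pitch.
#' @return A correspondence data.frame: `node_id`, `x`, `y` (reference,
#'   mm), `x1`, `y1` (registered detected position, mm), `plane_d_mm`,
#'   `response`. Unmatched node ids are in `attr(, "unmatched")`.
#' @export
match_nodes <- function(detected, lattice, center,
                        gate_mm = lattice$pitch_mm / 2) {
  stopifnot(inherits(lattice, "node_lattice"))
  xd <- detected$x_mm - center$x_mm
  yd <- detected$y_mm - center$y_mm
  nodes <- lattice$nodes
  nl <- nrow(nodes); nd <- length(xd)
  if (nd == 0L) {
    out <- data.frame(node_id = integer(), x = numeric(), y = numeric(),
                      x1 = numeric(), y1 = numeric(),
                      plane_d_mm = numeric(), response = numeric())
    attr(out, "unmatched") <- nodes$node_id
    return(out)
  }
  dmat <- outer(nodes$x_mm, xd, "-")^2 + outer(nodes$y_mm, yd, "-")^2
  ok <- which(dmat <= gate_mm^2)
  ord <- ok[order(dmat[ok])]
  used_n <- logical(nl); used_d <- logical(nd)
  pair_n <- integer(0); pair_d <- integer(0)
  for (idx in ord) {
    i <- (idx - 1L) %% nl + 1L
    j <- (idx - 1L) %/% nl + 1L
    if (!used_n[i] && !used_d[j]) {
      used_n[i] <- TRUE; used_d[j] <- TRUE
      pair_n <- c(pair_n, i); pair_d <- c(pair_d, j)
    }
  }
  o <- order(pair_n)
  pair_n <- pair_n[o]; pair_d <- pair_d[o]
  out <- data.frame(node_id = nodes$node_id[pair_n],
                    x = nodes$x_mm[pair_n], y = nodes$y_mm[pair_n],
                    x1 = xd[pair_d], y1 = yd[pair_d])
  out$plane_d_mm <- sqrt((out$x1 - out$x)^2 + (out$y1 - out$y)^2)
  out$response <- detected$response[pair_d]
  attr(out, "unmatched") <- nodes$node_id[!used_n]
  out
}
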