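# Default geometry of the water-filled 3D-printed grid phantom: a 40 cm
# circular front face partly cut flat for stability, 22 cm thick along the
# slice axis, filled with a 10 mm lattice of square water cells separated by
# resin walls, a solid diamond marker at the center. The lattice radius
# (170 mm) and cut offset (150 mm) are fixed design constants: enumerating
# complete 10 mm cells inside that cut disc yields exactly 822 cells.
.phantom_defaults <- list(
  face_diameter_mm     = 400,
  cut_chord_offset_mm  = 150,
  thickness_mm         = 220,
  cell_pitch_mm        = 10,
  wall_thickness_mm    = 2,
  diamond_halfwidth_mm = 7,
  grid_inner_radius_mm = 170
)

#' Build a grid-phantom geometry specification
#'
#' Returns the parametric description of the grid phantom: a circular front
#' face (default 40 cm diameter) partly cut off on the 180-degree side, a
#' square lattice of water-filled cells separated by thin resin walls, and a
#' solid diamond positioning marker at the center. All lengths are in mm.
#' The phantom frame has its origin at the diamond center, +y pointing to
#' the 0-degree reference direction (angles increase clockwise), and z
#' increasing from foot to head.
#'
#' @param overrides Named list of fields to override; unknown names are an
#'   error. Fields: `face_diameter_mm`, `cut_chord_offset_mm`,
#'   `thickness_mm`, `cell_pitch_mm`, `wall_thickness_mm`,
#'   `diamond_halfwidth_mm`, `grid_inner_radius_mm`.
#' @return An object of class `phantom_spec` (a named list).
#' @examples
#' spec <- build_phantom()
#' spec$face_diameter_mm    # 400
#' build_phantom(list(cell_pitch_mm = 20))$cell_pitch_mm
#' @export
build_phantom <- function(overrides = list()) {
  spec <- .phantom_defaults
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm)))
      stop("overrides must be a named list", call. = FALSE)
    bad <- setdiff(nm, names(spec))
    if (length(bad))
      stop("unknown phantom field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    spec[nm] <- overrides
  }
  num <- vapply(spec, is.numeric, logical(1))
  if (!all(num))
    stop("all phantom fields must be numeric", call. = FALSE)
  pos <- unlist(spec) > 0
  if (!all(pos))
    stop("non-positive phantom dimension(s): ",
         paste(names(spec)[!pos], collapse = ", "), call. = FALSE)
  if (spec$cell_pitch_mm >= spec$grid_inner_radius_mm)
    stop("cell_pitch_mm must be smaller than grid_inner_radius_mm",
         call. = FALSE)
  if (spec$cut_chord_offset_mm >= spec$face_diameter_mm / 2)
    stop("cut_chord_offset_mm must be smaller than the face radius",
         call. = FALSE)
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Grid phantom specification (mm):\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Enumerate the phantom's unit cells and control-point lattice
#'
#' Enumerates every complete `cell_pitch_mm` x `cell_pitch_mm` cell whose
#' full extent lies inside the closed disc of radius `grid_inner_radius_mm`
#' and above the stability-cut chord at y = -`cut_chord_offset_mm`, together
#' with every grid intersection (node) bounding those cells. With the
#' default specification the cell count is exactly 822. Nodes are the
#' control points whose imaged positions are compared against their design
#' positions.
#'
#' @param spec A `phantom_spec` from [build_phantom()].
#' @return An object of class `node_lattice`: a list with `nodes`
#'   (data.frame `node_id`, `x_mm`, `y_mm`), `cells` (data.frame of cell
#'   center coordinates `cx_mm`, `cy_mm`), `center` (c(0, 0)) and
#'   `pitch_mm`.
#' @examples
#' lat <- build_lattice(build_phantom())
#' nrow(lat$cells)   # 822
#' @export
build_lattice <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$cell_pitch_mm
  R <- spec$grid_inner_radius_mm
  cut <- spec$cut_chord_offset_mm
  n <- ceiling(R / p) + 1L
  idx <- seq.int(-n, n - 1L)
  cells <- expand.grid(i = idx, j = idx)
  mx <- pmax(abs(cells$i), abs(cells$i + 1L)) * p
  my <- pmax(abs(cells$j), abs(cells$j + 1L)) * p
  keep <- (mx^2 + my^2 <= R^2 + 1e-9) & (cells$j * p >= -cut - 1e-9)
  cells <- cells[keep, , drop = FALSE]
  if (nrow(cells) == 0L)
    stop("phantom geometry admits zero complete cells", call. = FALSE)
  corners <- rbind(cbind(cells$i,      cells$j),
                   cbind(cells$i + 1L, cells$j),
                   cbind(cells$i,      cells$j + 1L),
                   cbind(cells$i + 1L, cells$j + 1L))
  corners <- unique(corners)
  ord <- order(corners[, 2L], corners[, 1L])
  corners <- corners[ord, , drop = FALSE]
  nodes <- data.frame(node_id = seq_len(nrow(corners)),
                      x_mm = corners[, 1L] * p,
                      y_mm = corners[, 2L] * p)
  cell_df <- data.frame(cx_mm = (cells$i + 0.5) * p,
                        cy_mm = (cells$j + 0.5) * p)
  rownames(cell_df) <- NULL
  structure(list(nodes = nodes, cells = cell_df, center = c(0, 0),
                 pitch_mm = p),
            class = "node_lattice")
}

#' @export
print.node_lattice <- function(x, ...) {
  cat(sprintf("Grid-phantom lattice: %d cells, %d nodes, pitch %g mm\n",
              nrow(x$cells), nrow(x$nodes), x$pitch_mm))
  invisible(x)
}

#' Select lattice nodes within a cumulative radius
#'
#' Returns all nodes whose Euclidean distance from the phantom center is at
#' most `r_mm` (a cumulative disc, not an annulus), matching the 5/10/15 cm
#' range definitions used for reporting.
#'
#' @param lattice A `node_lattice`.
#' @param r_mm Positive radius in mm.
#' @return Subset of `lattice$nodes`.
#' @export
nodes_within_radius <- function(lattice, r_mm) {
  stopifnot(inherits(lattice, "node_lattice"), is.numeric(r_mm), r_mm > 0)
  n <- lattice$nodes
  n[sqrt(n$x_mm^2 + n$y_mm^2) <= r_mm + 1e-9, , drop = FALSE]
}

#' Write / read a phantom specification as a flat key-value config
#'
#' @param spec A `phantom_spec`.
#' @param path File path for the YAML key-value config (mm units).
#' @return `write_phantom_config` returns `path` invisibly;
#'   `read_phantom_config` returns a `phantom_spec`.
#' @export
write_phantom_config <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  build_phantom(yaml::read_yaml(path))
}

#' Export the node lattice as CSV
#'
#' Writes `node_id, x_mm, y_mm` rows for every control point.
#'
#' @param lattice A `node_lattice`.
#' @param path Output CSV path.
#' @export
write_lattice_csv <- function(lattice, path) {
  stopifnot(inherits(lattice, "node_lattice"))
  utils::write.csv(lattice$nodes, path, row.names = FALSE)
  invisible(path)
}
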