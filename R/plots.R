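# Publication-shaped base-graphics figures for a report bundle.

#' Plot the distortion histogram
#'
#' @param histogram Data frame from [distortion_histogram()].
#' @param main Plot title.
#' @export
plot_distortion_histogram <- function(histogram,
                                      main = "Distortion distribution") {
  graphics::barplot(histogram$count,
                    names.arg = sprintf("%.1f-%.1f", histogram$bin_lo_mm,
                                        histogram$bin_hi_mm),
                    xlab = "Distortion (mm)", ylab = "Control points",
                    main = main, las = 2)
  invisible(NULL)
}

#' Plot the distortion vector field
#'
#' Quiver-style plot of per-node displacement vectors, scaled for
#' visibility.
#'
#' @param field Data frame from [export_field()].
#' @param scale Arrow magnification.
#' @param main Plot title.
#' @export
plot_vector_field <- function(field, scale = 20,
                              main = "Distortion vectors") {
  graphics::plot(field$x, field$y, asp = 1, pch = 16, cex = 0.3,
                 col = "grey60", xlab = "x (mm)", ylab = "y (mm)",
                 main = main)
  nz <- field$d_mm > 0
  graphics::arrows(field$x[nz], field$y[nz],
                   field$x[nz] + scale * field$dx[nz],
                   field$y[nz] + scale * field$dy[nz],
                   length = 0.03, col = "firebrick")
  invisible(NULL)
}

#' Scatter plot of distortion against radius
#'
#' @param field Data frame from [export_field()].
#' @param main Plot title.
#' @export
plot_distortion_scatter <- function(field,
                                    main = "Distortion vs radius") {
  r <- sqrt(field$x^2 + field$y^2)
  graphics::plot(r, field$d_mm, pch = 16, cex = 0.4,
                 xlab = "Distance from center (mm)",
                 ylab = "Distortion (mm)", main = main)
  invisible(NULL)
}

#' Write the standard figures of a report bundle as PNG
#'
#' @param bundle Bundle from [run_pipeline()].
#' @param out_dir Output directory.
#' @export
plot_bundle_figures <- function(bundle, out_dir) {
  fig <- function(name, expr) {
    grDevices::png(file.path(out_dir, name), width = 900, height = 700)
    on.exit(grDevices::dev.off())
    expr
  }
  fig("histogram.png", plot_distortion_histogram(bundle$histogram))
  fig("vectors.png", plot_vector_field(bundle$field_table))
  fig("scatter.png", plot_distortion_scatter(bundle$field_table))
  invisible(NULL)
}
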