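# Shared fixtures, memoized so expensive renders happen once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixtures)) assign(name, fun(), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_spec <- function() fixture("spec", build_phantom)
default_lattice <- function() fixture("lattice",
                                      function() build_lattice(default_spec()))

ge_reference <- function() fixture("ge_ref", function()
  render_reference(default_spec(), protocol_preset("ge_hde"), 0))

# detection on the reference slice, matched to the lattice
ge_reference_corr <- function() fixture("ge_ref_corr", function() {
  spec <- default_spec()
  vol <- ge_reference()
  ctr <- find_center_marker(vol, spec)
  det <- detect_nodes(vol, spec, center = ctr)
  corr <- match_nodes(det, default_lattice(), ctr)
  attr(corr, "center") <- ctr
  corr
})

# small synthetic correspondence table with known geometry
toy_correspondences <- function(r = c(30, 70, 120), d = c(1, 2, 3)) {
  data.frame(node_id = seq_along(r), x = r, y = 0, x1 = r + d, y1 = 0,
             plane_d_mm = d, response = 1)
}

# identical-geometry per-slice correspondences for slice-tracking tests
stack_correspondences <- function(n_slices, dz = 5,
                                  lattice = default_lattice(),
                                  jitter_fun = NULL) {
  z <- (seq_len(n_slices) - 1) * dz
  corrs <- lapply(seq_len(n_slices), function(si) {
    n <- lattice$nodes
    x1 <- n$x_mm; y1 <- n$y_mm
    if (!is.null(jitter_fun)) {
      j <- jitter_fun(n$x_mm, n$y_mm, z[si])
      x1 <- x1 + j$dx; y1 <- y1 + j$dy
    }
    data.frame(node_id = n$node_id, x = n$x_mm, y = n$y_mm,
               x1 = x1, y1 = y1,
               plane_d_mm = sqrt((x1 - n$x_mm)^2 + (y1 - n$y_mm)^2),
               response = 1)
  })
  list(corrs = corrs, z = z)
}
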