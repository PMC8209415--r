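test_that("protocol presets carry the printed scanner parameters", {
  u <- protocol_preset("unity")
  expect_equal(u$fov_mm, 537.6)
  expect_equal(u$matrix, 1008L)
  expect_equal(u$pixel_bandwidth_hz_per_px, 1033)
  g1 <- protocol_preset("ge_hde")
  expect_equal(g1$fov_mm, 480)
  expect_equal(g1$pixel_bandwidth_hz_per_px, 195.31)
  expect_equal(g1$slice_thickness_mm, 5)
  expect_equal(pixel_size_mm(g1), 0.9375)
  g2 <- protocol_preset("ge_750")
  expect_equal(g2$fov_mm, 500)
  expect_equal(g2$slice_thickness_mm, 3)
  expect_error(protocol_preset("philips"))
})

test_that("displacement field evaluates the GNL + B0 model", {
  p <- protocol_preset("ge_hde")
  zero <- field_preset("zero")
  expect_equal(unlist(displacement_at(zero, p, c(123, -45, 6))),
               c(dx = 0, dy = 0, dz = 0))
  # a B0 of 195.31 Hz at the evaluation point under 195.31 Hz/px and a
  # 0.9375 mm pixel is exactly a one-pixel shift along the readout axis
  m <- distortion_model(b0 = parabolic_b0(195.31, r_ref_mm = 170))
  d <- displacement_at(m, p, c(170, 0, 0))
  expect_equal(d$dx, 0.9375)
  expect_equal(d$dy, 0)
  expect_equal(d$dz, 0)
})

test_that("B0 displacement scales exactly inversely with pixel bandwidth", {
  m <- distortion_model(b0 = parabolic_b0(80))
  # same raster, bandwidth is the only difference
  p_hi <- scan_protocol("hi", 480, 512, 1033, 5)
  p_lo <- scan_protocol("lo", 480, 512, 195.31, 5)
  pts <- data.frame(x = c(50, -120, 30), y = c(80, 10, -90), z = c(0, 4, -7))
  d_hi <- displacement_at(m, p_hi, pts)
  d_lo <- displacement_at(m, p_lo, pts)
  expect_equal(d_lo$dx / d_hi$dx, rep(1033 / 195.31, 3))
})

test_that("GNL field is linear in its coefficients and radial by design", {
  p <- protocol_preset("ge_750")
  g1 <- radial_gnl(1)
  g3 <- radial_gnl(3)
  m1 <- distortion_model(gnl = g1)
  m3 <- distortion_model(gnl = g3)
  pts <- data.frame(x = c(10, 100, -60), y = c(5, -50, 140), z = c(0, 3, -8))
  expect_equal(as.matrix(displacement_at(m3, p, pts)),
               3 * as.matrix(displacement_at(m1, p, pts)))
  # magnitude at the reference radius equals dmax
  d <- displacement_at(m3, p, c(170, 0, 0))
  expect_equal(sqrt(sum(d^2)), 3)
})

test_that("isocenter displacement is exactly zero for every model", {
  p <- protocol_preset("unity")
  models <- list(field_preset("unity_like"), field_preset("ge_750_like"),
                 distortion_model(gnl = radial_gnl(2), b0 = parabolic_b0(50)))
  for (m in models)
    expect_equal(unlist(displacement_at(m, p, c(0, 0, 0))),
                 c(dx = 0, dy = 0, dz = 0))
  expect_error(distortion_model(b0 = poly_const <- data.frame(
    i = 0L, j = 0L, k = 0L, c = 5)), "isocenter")
})

test_that("ground-truth displacement table covers every node and slice", {
  lat <- default_lattice()
  p <- protocol_preset("ge_hde")
  td0 <- true_displacements(field_preset("zero"), p, lat)
  expect_equal(nrow(td0), nrow(lat$nodes))
  expect_true(all(td0$dx_mm == 0 & td0$dy_mm == 0 & td0$dz_mm == 0))
  td <- true_displacements(field_preset("ge_750_like"), p, lat,
                           slice_z = c(-10, 0, 10))
  expect_equal(nrow(td), 3 * nrow(lat$nodes))
  ctr <- td[td$x_mm == 0 & td$y_mm == 0 & td$z_mm == 0, ]
  expect_equal(unlist(ctr[, c("dx_mm", "dy_mm", "dz_mm")]),
               c(dx_mm = 0, dy_mm = 0, dz_mm = 0))
})

test_that("reference rendering is deterministic with CT-like contrast", {
  spec <- default_spec()
  p <- protocol_preset("ge_hde")
  vol <- ge_reference()
  expect_identical(vol$data, render_reference(spec, p, 0)$data)
  # the diamond marker is solid resin at the center voxel; a cell interior
  # is water
  px <- vol$pixel_size_mm
  at <- function(x, y) vol$data[round((y - vol$origin_mm[2]) / px) + 1,
                                round((x - vol$origin_mm[1]) / px) + 1, 1]
  expect_gt(at(0, 0), 900)
  expect_lt(at(5, 5), 100)
  expect_equal(at(225, 0), 0)  # outside the phantom face: air
})

test_that("phantom larger than the FOV is rejected", {
  p <- scan_protocol("tiny", 300, 64, 200, 5)
  expect_error(render_reference(default_spec(), p, 0), "field of view")
})

test_that("MR rendering inverts contrast and respects the noise seed", {
  spec <- default_spec()
  p <- protocol_preset("ge_hde")
  m <- field_preset("zero", seed = 7)
  mr <- render_mr(spec, p, m, snr = Inf)
  ref <- ge_reference()
  px <- mr$pixel_size_mm
  at <- function(v, x, y) v$data[round((y - v$origin_mm[2]) / px) + 1,
                                 round((x - v$origin_mm[1]) / px) + 1, 1]
  expect_lt(at(mr, 0, 0), 100)   # resin dark on T2
  expect_gt(at(mr, 5, 5), 900)   # water bright on T2
  expect_gt(at(ref, 0, 0), 900)  # inverted versus CT
  n1 <- render_mr(spec, p, m, snr = 20)
  n2 <- render_mr(spec, p, m, snr = 20)
  expect_identical(n1$data, n2$data)
  m2 <- field_preset("zero", seed = 8)
  n3 <- render_mr(spec, p, m2, snr = 20)
  expect_false(identical(n1$data, n3$data))
  # different seeds differ only in noise: the difference has no structure
  # above the noise scale
  expect_lt(max(abs(n1$data - n3$data)), 10 * (1000 / 20))
})

test_that("a rigid-shift field translates the image content by the shift", {
  spec <- default_spec()
  p <- protocol_preset("ge_hde")
  shift <- c(5, -3)
  gnl <- list(x = data.frame(i = 0L, j = 0L, k = 0L, c = shift[1]),
              y = data.frame(i = 0L, j = 0L, k = 0L, c = shift[2]))
  m <- distortion_model(gnl = gnl, enforce_isocenter = FALSE)
  mr <- render_mr(spec, p, m, snr = Inf)
  ctr <- find_center_marker(mr, spec)
  expect_equal(ctr$x_mm, shift[1], tolerance = 0.1 / shift[1])
  expect_equal(ctr$y_mm, shift[2], tolerance = 0.1 / abs(shift[2]))
})

test_that("volumes round-trip through NIfTI", {
  spec <- default_spec()
  p <- scan_protocol("small", 480, 96, 200, 5, n_slices = 3)
  vol <- render_reference(spec, p, c(-5, 0, 5), supersample = 2)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$pixel_size_mm, vol$pixel_size_mm, tolerance = 1e-6)
  expect_equal(back$slice_positions_mm, vol$slice_positions_mm,
               tolerance = 1e-6)
})
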