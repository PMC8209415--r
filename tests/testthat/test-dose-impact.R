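test_that("default ROI layout has 14 squares plus the phantom disc", {
  rois <- default_rois()
  squares <- Filter(function(r) r$type == "square", rois)
  expect_length(squares, 14)
  p <- squares[[1]]
  expect_equal(p$label, "p")
  expect_equal(2 * p$half_mm, 20)
  expect_length(Filter(function(r) startsWith(r$label, "p3"), squares), 3)
  expect_length(Filter(function(r) startsWith(r$label, "p4"), squares), 2)
  expect_equal(rois[[length(rois)]]$type, "disc")
  # all square ROIs lie inside the phantom face and above the cut
  for (r in squares) {
    expect_lt(sqrt(r$x_mm^2 + r$y_mm^2) + r$half_mm * sqrt(2), 200)
    expect_gt(r$y_mm - r$half_mm, -150 - 1e-9)
  }
})

test_that("mean dose is exact on uniform and linear dose grids", {
  g_uniform <- dose_grid(matrix(50, 256, 256), 2)
  for (roi in default_rois())
    expect_equal(mean_dose(g_uniform, roi), 50)
  # linear ramp along x: symmetric ROI mean equals the ROI-center value
  px <- 2
  ax <- (seq_len(128) - 1 - 127 / 2) * px
  ramp <- matrix(100 + 0.2 * ax, 128, 128, byrow = TRUE)  # columns = x
  g_ramp <- dose_grid(ramp, px)
  roi <- roi_square("t", 30, -40, 10)
  expect_equal(mean_dose(g_ramp, roi), 100 + 0.2 * 30, tolerance = 1e-12)
})

test_that("dose change rate is zero for zero fields and uniform dose", {
  g <- synthetic_dose(matrix_px = 256, fov_mm = 480)
  zero_field <- field_from_model(field_preset("zero"),
                                 protocol_preset("ge_hde"))
  rates <- dose_impact_table(g, zero_field, default_rois())
  expect_equal(max(rates$change_rate_pct), 0)
  # uniform dose: any displacement changes nothing
  gu <- dose_grid(matrix(50, 256, 256), 480 / 256)
  shift <- function(points) data.frame(dx = rep(2, nrow(points)),
                                       dy = rep(-1, nrow(points)))
  expect_equal(dose_change_rate(gu, roi_square("p", 0, 0, 10), shift), 0)
})

test_that("rigid shift on a linear ramp matches the analytic change rate", {
  px <- 480 / 256
  ax <- (seq_len(256) - 1 - 255 / 2) * px
  g_slope <- 0.15  # Gy per mm
  base <- 60
  ramp <- matrix(base + g_slope * ax, 256, 256, byrow = TRUE)
  grid <- dose_grid(ramp, px)
  s <- 2.5  # mm shift along the ramp
  shift <- function(points) data.frame(dx = rep(s, nrow(points)),
                                       dy = rep(0, nrow(points)))
  roi <- roi_square("p", 0, 0, 10)
  analytic <- 100 * g_slope * s / base
  got <- dose_change_rate(grid, roi, shift)
  expect_equal(got, analytic, tolerance = 1e-3)
})

test_that("change rate is invariant to rescaling the dose grid", {
  g1 <- synthetic_dose(matrix_px = 256, fov_mm = 480, target_radius_mm = 100,
                       penumbra_mm = 30)
  g2 <- dose_grid(3.7 * g1$dose, g1$pixel_size_mm,
                  prescription_gy = 3.7 * 50)
  field <- field_from_model(field_preset("ge_750_like"),
                            protocol_preset("ge_hde"))
  roi <- roi_square("edge", 0, 100, 5)
  expect_equal(dose_change_rate(g1, roi, field),
               dose_change_rate(g2, roi, field), tolerance = 1e-12)
})

test_that("small distortion fields produce small dose changes", {
  g <- synthetic_dose(matrix_px = 256, fov_mm = 480)
  field <- field_from_model(field_preset("ge_750_like"),
                            protocol_preset("ge_750"))
  rates <- dose_impact_table(g, field)
  expect_lt(max(rates$change_rate_pct), 5)
})

test_that("whole-phantom rate agrees with a brute-force voxel sum", {
  g <- synthetic_dose(matrix_px = 256, fov_mm = 480, target_radius_mm = 120,
                      penumbra_mm = 40)
  model <- field_preset("ge_750_like")
  protocol <- protocol_preset("ge_hde")
  roi <- roi_disc("phantom", 0, 0, 170)
  got <- dose_change_rate(g, roi, field_from_model(model, protocol))
  # independent recomputation from raw voxels
  w <- mrgridqa:::.roi_weights(g, roi)
  idx <- which(w > 0, arr.ind = TRUE)
  px <- g$pixel_size_mm
  x <- g$origin_mm[1] + (idx[, 2] - 1) * px
  y <- g$origin_mm[2] + (idx[, 1] - 1) * px
  d <- displacement_at(model, protocol, data.frame(x = x, y = y, z = 0))
  ref <- sum(w[idx] * g$dose[idx]) / sum(w[idx])
  disp <- sum(w[idx] * mrgridqa:::.interp_dose(g, x + d$dx, y + d$dy)) /
    sum(w[idx])
  expect_equal(got, 100 * abs(disp - ref) / ref, tolerance = 1e-12)
})

test_that("synthetic dose has the prescribed plateau and falls off", {
  g <- synthetic_dose(matrix_px = 512, fov_mm = 500)
  n <- 512
  ctr <- g$dose[n / 2, n / 2]
  expect_equal(ctr, 50)
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * g$pixel_size_mm
  edge <- g$dose[n / 2, which.max(ax)]
  expect_lt(edge, 0.01 * 50)
  prof <- g$dose[n / 2, (n / 2):n]
  expect_true(all(diff(prof) <= 1e-9))
})
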