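test_that("plane and 3D distances follow the distance formulas", {
  expect_equal(plane_distortion(0, 0, 0, 0), 0)
  expect_equal(plane_distortion(0, 0, 3, 4), 5)
  expect_equal(plane_distortion(1, 2, 7, -3), plane_distortion(7, -3, 1, 2))
  expect_equal(distortion_3d(0, 0, 0, 1, 2, 2), 3)
  expect_equal(distortion_3d(1, 2, 5, 4, 6, 5), plane_distortion(1, 2, 4, 6))
  expect_gte(distortion_3d(0, 0, 0, 3, 4, 2), plane_distortion(0, 0, 3, 4))
})

test_that("radial summary uses cumulative discs", {
  corr <- toy_correspondences()  # distances 30/70/120 mm, d = 1/2/3 mm
  s <- radial_summary(corr, c(50, 100, 150))
  expect_equal(s$n, c(1L, 2L, 3L))
  expect_equal(s$mean_mm, c(1, 1.5, 2))
  expect_equal(s$sd_mm[1], 0)
  # constant distortion: every row mean = c, sd = 0
  cc <- toy_correspondences(d = c(4, 4, 4))
  sc <- radial_summary(cc, c(50, 100, 150))
  expect_equal(sc$mean_mm, rep(4, 3))
  expect_equal(sc$sd_mm, rep(0, 3))
  # empty disc warns and omits the row
  expect_warning(s2 <- radial_summary(corr, c(10, 150)), "omitted")
  expect_equal(nrow(s2), 1L)
})

test_that("largest-radius row equals the whole-set mean and SD exactly", {
  set.seed(42)
  n <- 500L
  corr <- data.frame(x = runif(n, -150, 150), y = runif(n, -150, 150))
  corr$plane_d_mm <- rgamma(n, 2, 2)
  s <- radial_summary(corr, c(50, 100, 150, 300))
  last <- s[nrow(s), ]
  expect_identical(last$n, n)
  expect_identical(last$mean_mm, mean(corr$plane_d_mm))
  expect_identical(last$sd_mm, sd(corr$plane_d_mm))
})

test_that("threshold fraction counts strictly-below points", {
  expect_equal(fraction_below(c(1, 1, 3, 5), 2), 0.5)
  expect_equal(fraction_below(rep(5, 4), 2), 0)
  expect_equal(fraction_below(toy_correspondences(d = c(0, 0, 0))), 1)
  d <- rgamma(200, 2, 2)
  expect_equal(fraction_below(d, 2) + mean(d >= 2), 1)
})

test_that("histogram bins are half-open and conserve counts", {
  h <- distortion_histogram(c(0.6, 0.6, 0.6), 0.5)
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[h$bin_lo_mm == 0.5], 3)
  # boundary value lands in the upper bin
  h2 <- distortion_histogram(c(0.5), 0.5)
  expect_equal(h2$count[h2$bin_lo_mm == 0.5], 1)
  set.seed(7)
  d <- runif(50000, 0, 2.5)
  h3 <- distortion_histogram(d, 0.5)
  expect_equal(sum(h3$count), 50000)
  expect_true(all(abs(h3$count - 10000) < 400))
})

test_that("mark points follow the clockwise-from-+y convention", {
  mp <- mark_points()
  expect_equal(nrow(mp), 11)  # 12 requested, 180deg/15cm cut away
  at <- function(r, a) unlist(mp[mp$radius_mm == r & mp$angle_deg == a,
                                 c("x_mm", "y_mm")])
  expect_equal(at(50, 0), c(x_mm = 0, y_mm = 50))
  expect_equal(at(50, 90), c(x_mm = 50, y_mm = 0))
  expect_equal(at(100, 180), c(x_mm = 0, y_mm = -100))
  expect_equal(at(150, 270), c(x_mm = -150, y_mm = 0))
  expect_equal(nrow(mp[mp$radius_mm == 150 & mp$angle_deg == 180, ]), 0L)
})

test_that("layer selection follows the foot-first, head-most-of-group rule", {
  st30 <- stack_correspondences(30)
  prof <- track_slices(st30$corrs, st30$z, default_lattice(), n_layers = 30)
  expect_equal(sort(unique(prof$slice_index)), 1:30)
  st90 <- stack_correspondences(90, dz = 2)
  prof90 <- track_slices(st90$corrs, st90$z, default_lattice(),
                         n_layers = 30)
  expect_equal(sort(unique(prof90$slice_index)),
               c(1L, seq(6L, 90L, by = 3L)))
  expect_error(track_slices(st30$corrs[1:10], st30$z[1:10],
                            default_lattice()), "at least")
})

test_that("mark-point profiles are constant for a z-constant field", {
  st <- stack_correspondences(30, jitter_fun = function(x, y, z)
    list(dx = 0.002 * x, dy = -0.001 * y))
  prof <- track_slices(st$corrs, st$z, default_lattice())
  for (lab in unique(prof$label)) {
    p <- prof[prof$label == lab, ]
    expect_equal(diff(range(p$x_mm)), 0)
    expect_equal(diff(range(p$y_mm)), 0)
  }
})

test_that("3D summary of identical layers equals the layer spacing", {
  st <- stack_correspondences(30, dz = 5)
  prof <- track_slices(st$corrs, st$z, default_lattice())
  s <- mark_point_3d_summary(prof)
  pts <- s[s$angle != "average", ]
  expect_equal(pts$mean_mm, rep(5, nrow(pts)))
  expect_equal(pts$sd_mm, rep(0, nrow(pts)))
  expect_equal(pts$n, rep(29L, nrow(pts)))
  # in-plane-only mode removes the head-foot term entirely
  s0 <- mark_point_3d_summary(prof, z_mode = "in_plane_only")
  expect_equal(max(s0$mean_mm), 0)
})

test_that("3D summary matches a brute-force recomputation", {
  set.seed(11)
  st <- stack_correspondences(60, dz = 5, jitter_fun = function(x, y, z)
    list(dx = 1e-5 * x * z + 0.3 * sin(z / 40),
         dy = 1e-5 * y * z))
  lat <- default_lattice()
  prof <- track_slices(st$corrs, st$z, lat)
  s <- mark_point_3d_summary(prof)
  # independent recomputation: selected layers are 1, 4, 6, ..., 60
  sel <- c(1L, seq(4L, 60L, by = 2L))
  mp <- mark_points()
  for (i in seq_len(nrow(mp))) {
    node <- lat$nodes[lat$nodes$x_mm == mp$x_mm[i] &
                        lat$nodes$y_mm == mp$y_mm[i], ]
    vals <- numeric(0)
    for (j in seq_len(length(sel) - 1)) {
      cf <- st$corrs[[sel[j]]]; ch <- st$corrs[[sel[j + 1]]]
      rf <- cf[cf$node_id == node$node_id, ]
      rh <- ch[ch$node_id == node$node_id, ]
      vals <- c(vals, sqrt((rh$x1 - rf$x1)^2 + (rh$y1 - rf$y1)^2 +
                             (st$z[sel[j + 1]] - st$z[sel[j]])^2))
    }
    row <- s[s$angle == as.character(mp$angle_deg[i]) &
               s$radius_mm == mp$radius_mm[i], ]
    expect_equal(row$mean_mm, mean(vals))
    expect_equal(row$sd_mm, sd(vals))
  }
})

test_that("vector-field export is consistent with the correspondences", {
  corr <- toy_correspondences()
  f <- export_field(corr)
  expect_equal(nrow(f), nrow(corr))
  expect_equal(f$d_mm, plane_distortion(corr$x, corr$y, corr$x1, corr$y1))
  zero <- export_field(toy_correspondences(d = c(0, 0, 0)))
  expect_equal(max(abs(c(zero$dx, zero$dy, zero$d_mm))), 0)
})

test_that("radial means are non-decreasing for a radially growing field", {
  lat <- default_lattice()
  n <- lat$nodes
  r <- sqrt(n$x_mm^2 + n$y_mm^2)
  d <- 3 * (r / 170)^3
  th <- atan2(n$x_mm, n$y_mm)
  corr <- data.frame(x = n$x_mm, y = n$y_mm,
                     x1 = n$x_mm + d * sin(th), y1 = n$y_mm + d * cos(th))
  corr$plane_d_mm <- plane_distortion(corr$x, corr$y, corr$x1, corr$y1)
  s <- radial_summary(corr)
  expect_true(all(diff(s$mean_mm) >= 0))
})
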