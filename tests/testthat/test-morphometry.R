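test_that("volume fraction is exact on trivial masks and additive", {
  full <- binary_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
  none <- binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_identical(volume_fraction(full), 1)
  expect_identical(volume_fraction(none), 0)
  # tube in a fixed 60 x 20 x 20 box
  ph <- rasterize_tube(tube_segment(c(5, 10, 10), c(55, 10, 10), r = 3),
                       shape = c(21, 21, 61))
  expect_rel_error(volume_fraction(ph$mask), pi * 9 * 50 / (61 * 21 * 21),
                   0.05)
  # additivity over disjoint masks on the same field
  a <- array(FALSE, c(5, 5, 5)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(5, 5, 5)); b[4:5, , ] <- TRUE
  expect_equal(volume_fraction(binary_mask(a | b, c(1, 1, 1))),
               volume_fraction(binary_mask(a, c(1, 1, 1))) +
                 volume_fraction(binary_mask(b, c(1, 1, 1))))
})

test_that("isosurface area matches analytic sphere and cylinder", {
  ball <- make_ball(r = 10, h = 1)
  a1 <- surface_area(ball)
  expect_rel_error(a1, 4 * pi * 100, 0.05)
  # halving the spacing does not increase the error
  ah <- surface_area(make_ball(r = 10, h = 0.5))
  expect_lte(abs(ah / (4 * pi * 100) - 1), abs(a1 / (4 * pi * 100) - 1))

  tube <- rasterize_tube(tube_segment(c(0, 0, 0), c(50, 0, 0), r = 3))$mask
  expect_rel_error(surface_area(tube), 2 * pi * 3 * 50 + 2 * pi * 9, 0.08)

  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_gt(surface_area(binary_mask(one, c(1, 1, 1))), 0)
  expect_warning(
    expect_identical(surface_area(binary_mask(array(FALSE, c(3, 3, 3)),
                                              c(1, 1, 1))), 0),
    "empty")
})

test_that("fibre length sums consecutive distances", {
  p <- structure(cbind(0:50, 0, 0), step_um = 1, class = "fibre_path")
  expect_equal(fibre_length(p), 50)
  expect_error(fibre_length(rbind(c(1, 2, 3))), "at least 2")
  expect_error(fibre_length(rbind(c(1, 2, 3), c(1, 2, 3))), "zero length")
})

test_that("curvature obeys the circle chord identity and rigid invariance", {
  # collinear points: exactly zero
  p <- structure(cbind(0:20, 0, 0), step_um = 1, class = "fibre_path")
  expect_identical(fibre_curvature(p), 0)
  # circle R = 10 sampled exactly at 1 um arc steps
  R <- 10
  k <- 0:62
  circ <- structure(cbind(R * cos(k / R), R * sin(k / R), 0),
                    step_um = 1, class = "fibre_path")
  # the flanking-interval denominator makes the estimate exactly 1/R on a
  # circle; the plain-second-difference chord value differs by O((ds/R)^2)
  expect_equal(fibre_curvature(circ), 1 / R, tolerance = 1e-9)
  expect_rel_error(fibre_curvature(circ), 2 * R * (1 - cos(1 / R)), 0.001)
  # rigid motion leaves curvature unchanged up to floating point
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- structure(unclass(circ) %*% rot +
                       matrix(c(5, -3, 11), nrow(circ), 3, byrow = TRUE),
                     step_um = 1, class = "fibre_path")
  expect_equal(fibre_curvature(moved), fibre_curvature(circ),
               tolerance = 1e-12)
  # fewer than 3 points: undefined, never zero
  expect_true(is.na(fibre_curvature(structure(cbind(0:1, 0, 0),
                                              step_um = 1,
                                              class = "fibre_path"))))
})

test_that("helix curvature at 1 um sampling matches the dense oracle", {
  a <- 4; cp <- 3
  # analytic helix arc-length parametrization: speed is sqrt(a^2 + c^2)
  speed <- sqrt(a^2 + cp^2)
  s <- seq(0, 60, by = 1)
  hel <- structure(cbind(a * cos(s / speed), a * sin(s / speed),
                         cp * s / speed),
                   step_um = 1, class = "fibre_path")
  est <- fibre_curvature(hel)
  # dense numerical oracle on the same analytic curve
  sd <- seq(0, 60, by = 0.01)
  dense <- cbind(a * cos(sd / speed), a * sin(sd / speed), cp * sd / speed)
  d1 <- diff(dense) / 0.01
  d2 <- diff(d1) / 0.01
  oracle <- mean(sqrt(rowSums(d2^2)))
  expect_rel_error(est, oracle, 0.02)
  expect_rel_error(est, a / (a^2 + cp^2), 0.02) # 0.16 exactly
})

test_that("equivalent diameter recovers 2r for straight and diagonal tubes", {
  for (r in c(2, 3, 4)) {
    ph <- rasterize_tube(tube_segment(c(0, 0, 0), c(40, 0, 0), r = r))
    res <- single_fibre_path(ph$mask)
    d_sec <- fibre_diameter(res$path, res$skel)
    d_edt <- fibre_diameter(res$path, res$skel, method = "edt")
    expect_lt(abs(d_sec - 2 * r), 1) # within one voxel
    expect_lt(abs(d_sec - d_edt), 1) # estimators agree within one voxel
    phd <- rasterize_tube(tube_segment(c(0, 0, 0), c(25, 25, 25), r = r))
    resd <- single_fibre_path(phd$mask)
    expect_lt(abs(fibre_diameter(resd$path, resd$skel) - 2 * r), 1)
  }
})

test_that("diameter is defined for a two-point path via end tangents", {
  ph <- rasterize_tube(tube_segment(c(0, 0, 0), c(12, 0, 0), r = 2))
  sk <- skeletonize(ph$mask)
  g <- prune_spurs(build_graph(sk))
  p <- g$edges[[1]]$path
  two <- structure(p[c(1, nrow(p)), ], step_um = NULL, class = "fibre_path")
  expect_lt(abs(fibre_diameter(two, sk) - 4), 1)
})

test_that("channel intensity ratio is the ratio of masked means", {
  a <- array(FALSE, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- TRUE
  m <- binary_mask(a, c(1, 1, 1))
  den <- array(runif(64, 10, 50), c(4, 4, 4))
  expect_equal(channel_intensity_ratio(m, 2 * den, den), 2)
  expect_equal(channel_intensity_ratio(m, den, den), 1)
  expect_error(channel_intensity_ratio(m, den, den * 0), "zero")
  empty <- binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(channel_intensity_ratio(empty, den, den), "empty")
  expect_error(channel_intensity_ratio(m, array(1, c(4, 4, 2)), den),
               "grid")
})

test_that("analyze_field recovers a straight tube end to end", {
  ph <- rasterize_tube(tube_segment(c(0, 0, 0), c(50, 0, 0), r = 3))
  st <- render_acquisition(ph$mask,
                           imaging_model(psf_sigma = c(0, 0, 0), seed = 1))
  fm <- analyze_field(st)
  expect_false(fm$empty)
  expect_identical(fm$n_fibres, 1L)
  expect_identical(fm$n_branches, 0L)
  expect_rel_error(fm$lengths_um[1], 50, 0.03)
  expect_lt(abs(fm$diameters_um[1] - 6), 1)
  expect_lt(field_curvature(fm), 0.01)
  expect_rel_error(fm$volume_fraction * prod(dim(ph$mask$voxels)),
                   pi * 9 * 50, 0.05)
})

test_that("analyze_field flags an empty field explicitly", {
  blank <- image_stack(array(c(0, rep(1, 999)), c(10, 10, 10)),
                       c(1, 1, 1), "tropoelastin")
  fm <- analyze_field(blank, default_config(
    segmentation = list(min_volume_um3 = 2000)))
  expect_true(fm$empty)
  expect_identical(fm$n_fibres, 0L)
  expect_identical(fm$volume_fraction, 0)
})

test_that("analyze_field counts candelabra prongs under mild noise", {
  ph <- make_candelabra(4, jitter_sd = 0.5, seed = 42)
  st <- render_acquisition(ph$mask,
                           imaging_model(psf_sigma = c(0.8, 0.4, 0.4),
                                         gaussian_sd = 5, seed = 7))
  fm <- analyze_field(st)
  expect_identical(fm$n_branches, 4L)
  # field metrics carry the resolved configuration for provenance
  expect_s3_class(fm$config, "fm_config")
  expect_error(analyze_field(st, list(bogus = 1)), "unknown config key")
})

test_that("pipeline parameter recovery holds across arc radii and calibres", {
  for (R in c(8, 15, 30)) {
    ph <- rasterize_tube(tube_arc(c(0, 0, 0), radius = R, r = 3))
    res <- single_fibre_path(ph$mask)
    expect_rel_error(fibre_curvature(res$path), 1 / R, 0.10)
    expect_identical(branch_count(res$graph), 0L)
    expect_lt(abs(fibre_diameter(res$path, res$skel) - 6), 1)
  }
})
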