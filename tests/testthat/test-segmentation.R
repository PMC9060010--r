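test_that("preprocess is the identity for sigma 0 and conserves mass", {
  ch <- array(runif(6 * 6 * 6), c(6, 6, 6))
  expect_identical(preprocess(ch, c(1, 1, 1)), ch)
  # constant image unchanged (reflective boundaries leak nothing)
  const <- array(7, c(8, 8, 8))
  expect_equal(preprocess(const, c(1, 1, 1), smooth_sigma_um = c(1, 1, 1)),
               const, tolerance = 1e-12)
  # interior impulse: Gaussian mass conserved within 1%
  imp <- array(0, c(15, 15, 15))
  imp[8, 8, 8] <- 1
  out <- preprocess(imp, c(1, 1, 1), smooth_sigma_um = c(1, 1, 1))
  expect_rel_error(sum(out), 1, 0.01)
  expect_error(preprocess(ch, c(1, 1, 1), smooth_sigma_um = c(-1, 0, 0)),
               ">= 0")
})

test_that("background subtraction removes a smooth pedestal", {
  ch <- array(50, c(10, 20, 20))
  ch[5, 9:11, 9:11] <- 150
  out <- preprocess(ch, c(1, 1, 1), background_radius_um = 5)
  # pedestal suppressed, fibre-like peak retained
  expect_lt(median(out), 1e-9)
  expect_gt(out[5, 10, 10], 50)
})

test_that("Otsu threshold maximizes between-class variance (brute-force)", {
  withr::local_seed(3)
  x <- c(rnorm(400, 10, 1.5), rnorm(150, 100, 6))
  thr <- otsu_threshold(x)
  expect_gt(thr, 10)
  expect_lt(thr, 100)
  # independent oracle: scan every candidate split of the same 256-bin grid
  breaks <- seq(min(x), max(x), length.out = 257)
  bcv <- vapply(breaks[2:256], function(t) {
    w0 <- mean(x <= t)
    if (w0 == 0 || w0 == 1) return(-Inf)
    w0 * (1 - w0) * (mean(x[x <= t]) - mean(x[x > t]))^2
  }, 0)
  best <- breaks[1 + which.max(bcv)]
  # binned criterion vs exact within-bin means: agree to one bin width
  expect_lt(abs(thr - best), diff(range(x)) / 256 + 1e-9)
  expect_error(otsu_threshold(rep(4, 10)), "constant")
})

test_that("binarize separates a two-level image exactly", {
  ch <- array(10, c(6, 8, 8))
  fg <- array(FALSE, dim(ch))
  fg[3:4, 3:6, 3:6] <- TRUE
  ch[fg] <- 100
  m <- binarize(ch, c(1, 1, 1))
  expect_identical(m$voxels, fg)
  thr <- attr(m, "threshold")
  expect_true(thr > 10 && thr < 100)
  # fixed threshold on a 0/1 image
  bin01 <- array(as.numeric(fg), dim(fg))
  expect_identical(binarize(bin01, c(1, 1, 1), method = 0.5)$voxels, fg)
  expect_error(binarize(array(5, c(3, 3, 3)), c(1, 1, 1)), "constant")
  expect_warning(binarize(ch, c(1, 1, 1), method = 1000), "outside")
})

test_that("thresholding is monotone in the threshold", {
  withr::local_seed(8)
  ch <- array(runif(5 * 6 * 7, 0, 100), c(5, 6, 7))
  lo <- binarize(ch, c(1, 1, 1), method = 20)$voxels
  hi <- suppressWarnings(binarize(ch, c(1, 1, 1), method = 60)$voxels)
  expect_true(all(lo[hi])) # raising the threshold never adds voxels
})

test_that("remove_small_components keeps only large structures", {
  a <- array(FALSE, c(10, 20, 20))
  a[4:6, 3:12, 3:12] <- TRUE # 300 um^3 block
  a[2, 16, 16] <- TRUE       # 1 um^3 speckle
  m <- binary_mask(a, c(1, 1, 1))
  out <- remove_small_components(m, min_volume_um3 = 50)
  expect_identical(sum(out$voxels), 300L)
  # min = 0 is the identity
  expect_identical(remove_small_components(m, 0)$voxels, a)
  # idempotent and anti-extensive
  out2 <- remove_small_components(out, 50)
  expect_identical(out2$voxels, out$voxels)
  expect_true(all(a[out$voxels]))
})

test_that("a tube survives speckle removal among many random speckles", {
  withr::local_seed(12)
  ph <- rasterize_tube(tube_segment(c(5, 20, 20), c(35, 20, 20), r = 2.5),
                       shape = c(41, 41, 41))
  a <- ph$mask$voxels
  free <- which(!a)
  a[sample(free, 100)] <- TRUE # isolated (mostly 1-voxel) speckles
  cleaned <- remove_small_components(binary_mask(a, c(1, 1, 1)),
                                     min_volume_um3 = 30)
  # exactly the tube's component survives (speckles touching it may persist)
  expect_gte(sum(cleaned$voxels), sum(ph$mask$voxels))
  lab <- fibremorph:::cpp_label_components(as.logical(cleaned$voxels),
                                           dim(a), 26L)
  expect_identical(max(lab), 1L)
})

test_that("Otsu recovers a noise-free rendered phantom mask exactly", {
  ph <- make_candelabra(3, jitter_sd = 0, seed = 5)
  st <- render_acquisition(ph$mask,
                           imaging_model(psf_sigma = c(0, 0, 0), seed = 1))
  m <- binarize(st$voxels$tropoelastin, st$spacing)
  expect_identical(m$voxels, ph$mask$voxels)
})

test_that("per-slice Otsu recovers strongly attenuated vertical fibres", {
  ph <- rasterize_tube(tube_segment(c(10, 10, 5), c(10, 10, 65), r = 3),
                       shape = c(73, 21, 21))
  st <- render_acquisition(ph$mask,
                           imaging_model(psf_sigma = c(0, 0, 0),
                                         attenuation_um = 20, seed = 2))
  global <- analyze_field(st)
  slice <- analyze_field(st, default_config(
    segmentation = list(per_slice = TRUE)))
  # global Otsu loses the dim deep half; slice-wise keeps nearly all of it
  expect_gt(sum(slice$lengths_um), sum(global$lengths_um))
  expect_rel_error(sum(slice$lengths_um), 60, 0.1)
})
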