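test_that("image_stack validates its invariants", {
  v <- array(0, c(4, 5, 6))
  s <- image_stack(v, c(0.8, 0.75, 0.75), "tropoelastin")
  expect_s3_class(s, "image_stack")
  expect_error(image_stack(list(v, v), c(1, 1, 1), "onlyone"),
               "channel count mismatch")
  expect_error(image_stack(v, c(0, 1, 1), "a"), "positive")
  expect_error(image_stack(array(-1, c(2, 2, 2)), c(1, 1, 1), "a"), ">= 0")
  expect_error(image_stack(list(v, array(0, c(4, 5, 7))), c(1, 1, 1),
                           c("a", "b")), "share one grid shape")
})

test_that("stack write/read round-trips multichannel integer data bit-exactly", {
  withr::local_seed(41)
  path <- withr::local_tempfile(fileext = ".tif")
  v16 <- array(sample(0:65535, 8 * 12 * 10, TRUE), c(8, 12, 10))
  v8 <- array(sample(0:255, 8 * 12 * 10, TRUE), c(8, 12, 10))
  s <- image_stack(list(v16, v8), spacing = c(0.8, 0.75, 0.75),
                   channels = c("tropoelastin", "fibrillin1"))
  write_stack(s, path)
  s2 <- suppressMessages(read_stack(path))
  expect_equal(s2$voxels$tropoelastin, v16, ignore_attr = FALSE,
               tolerance = 0)
  expect_equal(s2$voxels$fibrillin1, v8, tolerance = 0)
  expect_identical(s2$channels, s$channels)
  expect_equal(s2$spacing, s$spacing, tolerance = 1e-12)
})

test_that("non-integer stacks round-trip bit-exactly via 64-bit float pages", {
  withr::local_seed(42)
  path <- withr::local_tempfile(fileext = ".tif")
  v <- array(runif(6 * 7 * 8) * 3.7, c(6, 7, 8))
  s <- image_stack(v, c(0.8, 0.207, 0.207), "tropoelastin",
                   depth_origin = 2.4)
  write_stack(s, path)
  s2 <- suppressMessages(read_stack(path))
  expect_identical(s2$voxels$tropoelastin, v)
  expect_identical(s2$spacing, c(0.8, 0.207, 0.207))
  expect_identical(s2$depth_origin, 2.4)
})

test_that("read_stack resolves channel roles and spacing precedence", {
  path <- withr::local_tempfile(fileext = ".tif")
  s <- image_stack(list(array(1, c(3, 4, 4)), array(2, c(3, 4, 4)),
                        array(3, c(3, 4, 4))),
                   c(1, 1, 1), c("nuclei", "tropoelastin", "fibrillin1"))
  write_stack(s, path)
  # role-count mismatch against the stored 3 channels
  expect_error(suppressMessages(read_stack(path, channel_roles = c("a", "b"))),
               "channel count mismatch")
  # override wins over stored spacing, and says so
  expect_message(
    s2 <- read_stack(path, spacing_override = c(2, 0.5, 0.5)),
    "override")
  expect_identical(s2$spacing, c(2, 0.5, 0.5))
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "not found")
})

test_that("stacks written by other writers are read via the JSON sidecar", {
  # emulate a foreign TIFF: strip the embedded description, supply a sidecar
  path <- withr::local_tempfile(fileext = ".tif")
  v <- array(sample(0:100, 3 * 4 * 5, TRUE), c(3, 4, 5))
  fibremorph:::write_tiff_pages(path, lapply(1:3, function(z) v[z, , ]),
                                bits = 16L, sample_format = 1L)
  expect_error(read_stack(path, channel_roles = "tropoelastin"),
               "spacing")
  jsonlite::write_json(list(spacing = c(1, 0.5, 0.5), axes = "ZCYX"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  s <- suppressMessages(read_stack(path, channel_roles = "tropoelastin"))
  expect_equal(s$voxels$tropoelastin, v, tolerance = 0)
  expect_identical(s$spacing, c(1, 0.5, 0.5))
})

test_that("crop_to_depth implements the inclusive 100 um convention", {
  s <- image_stack(array(0, c(188, 4, 4)), c(0.8, 1, 1), "tropoelastin")
  cropped <- crop_to_depth(s, 100)
  expect_identical(dim(cropped$voxels[[1]])[1], 126L) # z = 0 ... 100.0 um
  # shallower stack than the limit is untouched
  s50 <- image_stack(array(0, c(50, 4, 4)), c(0.8, 1, 1), "tropoelastin")
  expect_identical(dim(crop_to_depth(s50, 100)$voxels[[1]])[1], 50L)
  s11 <- image_stack(array(0, c(30, 4, 4)), c(1, 1, 1), "tropoelastin")
  expect_identical(dim(crop_to_depth(s11, 10)$voxels[[1]])[1], 11L)
  # idempotent
  expect_identical(crop_to_depth(cropped, 100), cropped)
  # nothing left below the origin
  deep <- image_stack(array(0, c(10, 4, 4)), c(1, 1, 1), "tropoelastin",
                      depth_origin = 50)
  expect_error(crop_to_depth(deep, 20), "no slices")
})

test_that("metrics tables round-trip to full precision with explicit NA", {
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- rbind(
    metrics_record("s1", "young", "abdomen",
                   volume_fraction = 0.123456789012345,
                   mean_curvature_per_um = pi / 17),
    metrics_record("s2", "aged", "eyelid", n_branches = 3))
  write_metrics(recs, path)
  r2 <- read_metrics(path)
  expect_equal(r2$volume_fraction, recs$volume_fraction, tolerance = 1e-13)
  expect_true(is.na(r2$intensity_ratio[1])) # absent stays absent
  expect_true(is.na(r2$volume_fraction[2]))
  expect_error(metrics_record("x", bogus_metric = 1), "unknown metric")
  expect_error(metrics_record("x", volume_fraction = Inf), "finite")
})

test_that("random metrics records survive a write/read cycle field-wise", {
  withr::local_seed(7)
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- do.call(rbind, lapply(1:100, function(i) {
    metrics_record(sprintf("s%03d", i),
                   sample(c("young", "aged"), 1),
                   sample(c("abdomen", "eyelid"), 1),
                   volume_fraction = runif(1),
                   surface_area_um2 = rexp(1, 1e-4),
                   n_branches = rpois(1, 4),
                   mean_length_um = rlnorm(1, 3),
                   mean_curvature_per_um = runif(1, 0, 0.3),
                   intensity_ratio = if (i %% 3) runif(1, 0.2, 3) else NA)
  }))
  write_metrics(recs, path)
  r2 <- read_metrics(path)
  for (cl in names(recs))
    expect_equal(r2[[cl]], recs[[cl]], tolerance = 1e-13, label = cl)
})
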