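test_that("a straight tube skeletonizes to a single centred path", {
  ph <- rasterize_tube(tube_segment(c(0, 0, 0), c(40, 0, 0), r = 3))
  sk <- skeletonize(ph$mask)
  g <- prune_spurs(build_graph(sk))
  expect_identical(sum(g$nodes$kind == "endpoint"), 2L)
  expect_identical(sum(g$nodes$kind == "junction"), 0L)
  expect_length(g$edges, 1L)
  # refined centreline hugs the analytic axis (y = z = snapped centre row)
  g <- refine_centerline(g, sk, 2L)
  p <- g$edges[[1]]$path
  axis_yz <- p[1, 2:3]
  offaxis <- sqrt((p[, 2] - axis_yz[1])^2 + (p[, 3] - axis_yz[2])^2)
  expect_lt(sqrt(mean(offaxis^2)), 0.5)
  expect_error(skeletonize(binary_mask(array(FALSE, c(3, 3, 3)),
                                       c(1, 1, 1))), "empty")
})

test_that("skeletonization preserves topology and stays inside the mask", {
  for (mask in list(rasterize_tube(tube_arc(c(0, 0, 0), 15, r = 3))$mask,
                    rasterize_tree(make_y_tree())$mask)) {
    sk <- skeletonize(mask)
    expect_true(all(mask$voxels[sk$voxels])) # skeleton subset of mask
    d <- dim(mask$voxels)
    n_mask <- max(fibremorph:::cpp_label_components(
      as.logical(mask$voxels), d, 26L))
    n_skel <- max(fibremorph:::cpp_label_components(
      as.logical(sk$voxels), d, 26L))
    expect_identical(n_skel, n_mask)
  }
})

test_that("a solid ball collapses to a tiny skeleton", {
  ball <- make_ball(r = 10)
  sk <- skeletonize(ball)
  # a curve skeletonizer reduces the ball to a short path (a few voxels,
  # possibly one bump-induced ray; see the methods vignette), never a sheet
  expect_lt(sum(sk$voxels), 0.005 * sum(ball$voxels))
  d <- dim(ball$voxels)
  expect_identical(max(fibremorph:::cpp_label_components(
    as.logical(sk$voxels), d, 26L)), 1L)
})

test_that("a single voxel is its own skeleton and an isolated node", {
  a <- array(FALSE, c(5, 5, 5))
  a[3, 3, 3] <- TRUE
  sk <- skeletonize(binary_mask(a, c(1, 1, 1)))
  expect_identical(sk$voxels, a)
  g <- build_graph(sk)
  expect_identical(nrow(g$nodes), 1L)
  expect_identical(g$nodes$kind, "isolated")
  expect_length(g$edges, 0L)
})

test_that("the skeleton graph satisfies the handshake identity", {
  for (mask in list(rasterize_tree(make_y_tree())$mask,
                    rasterize_tree(make_depth3_tree())$mask,
                    make_candelabra(4, jitter_sd = 0.4, seed = 2)$mask)) {
    g <- build_graph(skeletonize(mask))
    deg <- fibremorph:::node_degrees(g)
    expect_identical(sum(deg), 2L * length(g$edges))
    # endpoint nodes have degree 1, junctions at least 3 (after pruning)
    gp <- prune_spurs(g)
    deg <- fibremorph:::node_degrees(gp)
    kinds <- setNames(gp$nodes$kind, gp$nodes$id)
    expect_true(all(deg[names(kinds)[kinds == "endpoint"]] == 1L))
    expect_true(all(deg[names(kinds)[kinds == "junction"]] >= 3L))
  }
})

test_that("Y and depth-3 trees give the expected graph structure", {
  gy <- prune_spurs(build_graph(skeletonize(rasterize_tree(make_y_tree())$mask)))
  expect_identical(sum(gy$nodes$kind == "endpoint"), 3L)
  expect_identical(sum(gy$nodes$kind == "junction"), 1L)
  expect_length(gy$edges, 3L)
  g3 <- prune_spurs(build_graph(skeletonize(
    rasterize_tree(make_depth3_tree())$mask)))
  expect_identical(branch_count(g3), 3L)
  expect_identical(sum(g3$nodes$kind == "endpoint"), 5L) # 4 leaves + root
  expect_length(g3$edges, 7L)
})

test_that("a closed tube ring becomes one anchored cycle edge", {
  th <- seq(0, 2 * pi, length.out = 200)
  ring <- cbind(15 + 10 * cos(th), 15 + 10 * sin(th), 6)
  vox <- fibremorph:::cpp_rasterize_tube(ring, 2.5, c(13, 31, 31),
                                         c(1, 1, 1), c(0, 0, 0))
  m <- binary_mask(array(vox, c(13, 31, 31)), c(1, 1, 1))
  g <- build_graph(skeletonize(m))
  expect_identical(sum(g$nodes$kind == "endpoint"), 0L)
  expect_identical(sum(g$nodes$kind == "junction"), 0L)
  expect_length(g$edges, 1L)
  e <- g$edges[[1]]
  expect_identical(e$from, e$to) # cycle anchored at one node
  expect_rel_error(fibremorph:::polyline_length(e$path), 2 * pi * 10, 0.1)
})

test_that("centre-of-gravity refinement recentres and is a fixed point", {
  ph <- rasterize_tube(tube_segment(c(0, 0, 0), c(40, 0, 0), r = 3))
  sk <- skeletonize(ph$mask)
  g <- prune_spurs(build_graph(sk))
  axis_y <- g$edges[[1]]$path[1, 2] # lattice row the axis sits on
  axis_z <- g$edges[[1]]$path[1, 3]
  # displace interior points by one voxel off-axis
  gbad <- g
  n <- nrow(gbad$edges[[1]]$path)
  gbad$edges[[1]]$path[2:(n - 1), 2] <- axis_y + 1
  rms <- function(gg) {
    p <- gg$edges[[1]]$path
    sqrt(mean((p[, 2] - axis_y)^2 + (p[, 3] - axis_z)^2))
  }
  gref <- refine_centerline(gbad, sk, 2L)
  expect_lt(rms(gref), rms(gbad))
  expect_lt(rms(gref), 0.5) # back within half a voxel of the axis
  # an already centred path barely moves
  gref2 <- refine_centerline(gref, sk, 2L)
  expect_lt(max(abs(gref2$edges[[1]]$path - gref$edges[[1]]$path)), 0.1)
})

test_that("refinement brings a quarter-arc centreline within half a voxel", {
  ph <- rasterize_tube(tube_arc(c(0, 0, 0), radius = 20, r = 3))
  tr <- trace_centerlines(ph$mask)
  p <- tr$graph$edges[[1]]$path
  # the arc centre was snapped to the lattice along with the geometry
  centre <- c(5, 5)
  radial <- sqrt((p[, 1] - centre[1])^2 + (p[, 2] - centre[2])^2) - 20
  expect_lt(sqrt(mean(radial^2)), 0.5)
})

test_that("arc-length resampling hits the stated point counts", {
  seg <- cbind(seq(0, 10, length.out = 41), 0, 0)
  fp <- resample_arclength(seg, 1)
  expect_identical(nrow(fp), 11L)
  expect_equal(as.numeric(diff(fp[, 1])), rep(1, 10), tolerance = 1e-9)

  seg2 <- cbind(seq(0, 10.4, length.out = 53), 0, 0)
  fp2 <- resample_arclength(seg2, 1)
  expect_identical(nrow(fp2), 12L)
  expect_equal(sqrt(sum((fp2[12, ] - fp2[11, ])^2)), 0.4, tolerance = 1e-9)

  # dense circle: resampled points stay on the circle
  th <- seq(0, 2 * pi, length.out = 2000)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  fp3 <- resample_arclength(circ, 1)
  d <- abs(sqrt(fp3[, 1]^2 + fp3[, 2]^2) - 10)
  expect_lt(max(d), 0.05)
  expect_error(resample_arclength(rbind(c(1, 1, 1), c(1, 1, 1))),
               "zero-length")
})

test_that("path smoothing is identity at window 1 and reduces jitter", {
  p <- cbind(0:20, 0, 0)
  fp <- structure(p, step_um = 1, class = "fibre_path")
  expect_identical(smooth_path(fp, 1L), fp)
  expect_equal(unclass(smooth_path(fp, 5L)), p,
               ignore_attr = TRUE) # collinear unchanged
  expect_error(smooth_path(fp, 4L), "odd")
  # jittered circle: RMS distance to the circle strictly reduced, 10 seeds
  th <- seq(0, 2 * pi, by = 0.1)
  for (s in 1:10) {
    withr::with_seed(s, {
      noisy <- cbind(10 * cos(th) + rnorm(length(th), 0, 0.2),
                     10 * sin(th) + rnorm(length(th), 0, 0.2), 0)
    })
    fpn <- structure(noisy, step_um = 1, class = "fibre_path")
    rms <- function(q) sqrt(mean((sqrt(q[, 1]^2 + q[, 2]^2) - 10)^2))
    expect_lt(rms(smooth_path(fpn, 5L)), rms(fpn))
  }
})

test_that("graph serialization writes JSON and SWC", {
  tr <- trace_centerlines(rasterize_tree(make_y_tree())$mask)
  jpath <- withr::local_tempfile(fileext = ".json")
  spath <- withr::local_tempfile(fileext = ".swc")
  graph_to_json(tr$graph, jpath)
  back <- jsonlite::fromJSON(jpath, simplifyVector = TRUE)
  expect_identical(nrow(back$nodes), nrow(tr$graph$nodes))
  expect_length(back$edges$id, length(tr$graph$edges))
  graph_to_swc(tr$graph, spath)
  swc <- read.table(spath, comment.char = "#")
  expect_identical(ncol(swc), 7L)
  expect_gt(nrow(swc), 10L)
})
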