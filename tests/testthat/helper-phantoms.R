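# shared fixtures: all phantoms are generated in code at test time

# full centreline pipeline on a mask, mirroring analyze_field's stages
trace_centerlines <- function(mask, prune_um = 3) {
  sk <- skeletonize(mask)
  g <- prune_spurs(build_graph(sk), prune_um)
  g <- refine_centerline(g, sk, 2L)
  g <- fibremorph:::extend_tips(g, sk)
  g <- refine_centerline(g, sk, 1L)
  list(graph = g, skel = sk)
}

# resampled + smoothed path of the single edge of a tube phantom
single_fibre_path <- function(mask, window = 7L) {
  tr <- trace_centerlines(mask)
  stopifnot(length(tr$graph$edges) == 1L)
  fp <- resample_arclength(tr$graph$edges[[1]]$path)
  list(path = smooth_path(fp, window), skel = tr$skel, graph = tr$graph)
}

# digital ball of radius r um at isotropic spacing h
make_ball <- function(r = 10, h = 1) {
  n <- 2L * as.integer(round((r + 2.5) / h)) + 1L # odd: centre on-lattice
  c0 <- (n - 1) / 2 * h
  pos <- (seq_len(n) - 1) * h
  d2 <- outer(outer((pos - c0)^2, (pos - c0)^2, `+`), (pos - c0)^2, `+`)
  binary_mask(array(d2 <= r^2, dim = c(n, n, n)), rep(h, 3))
}

# Y-shaped tree: one trunk, two limbs, one junction
make_y_tree <- function(r = 2.5) {
  tree_spec(rbind(c(0, 0, 0), c(20, 0, 0), c(35, 12, 0), c(35, -12, 0)),
            c(NA, 1L, 2L, 2L), r = r)
}

# binary tree of depth 3: 7 edges, 3 junctions
make_depth3_tree <- function(r = 2) {
  nodes <- rbind(c(0, 0, 0), c(18, 0, 0), c(32, 11, 0), c(32, -11, 0),
                 c(44, 17, 0), c(44, 5, 0), c(44, -5, 0), c(44, -17, 0))
  tree_spec(nodes, c(NA, 1L, 2L, 2L, 3L, 3L, 4L, 4L), r = r)
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value / truth - 1), tol)
}
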