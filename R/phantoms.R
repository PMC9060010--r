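# Synthetic tubular phantoms with analytic ground truth. These stand in for
# the (undeposited) human tissue stacks: every generated fibre has a known
# centreline geometry, radius and branch count, so the whole measurement
# pipeline can be validated against closed-form values.

#' Tube phantom specifications
#'
#' Constructors for parametric centreline geometries around which a tube of
#' radius `r` micrometres is rasterized. Analytic curvature of a circular arc
#' is `1/R`; of a helix with radius `a` and pitch parameter `c` (rise per
#' radian) it is `a / (a^2 + c^2)`.
#'
#' @param p0,p1 Segment endpoints, `(x, y, z)` micrometres.
#' @param r Tube radius in micrometres (> 0).
#' @param centre Arc/helix centre (arc) or axis base point (helix).
#' @param radius Arc radius `R` in micrometres; must exceed `2 r` so the tube
#'   cannot self-intersect.
#' @param span Angular span of the arc in radians (default `pi/2`).
#' @param start_angle Starting angle of the arc in radians.
#' @param plane Plane of the arc: `"xy"`, `"xz"` or `"yz"`.
#' @param a Helix radius in micrometres (> `2 r`).
#' @param c_pitch Helix rise per radian in micrometres.
#' @param turns Number of helix turns (> 0).
#' @param points An n-by-3 matrix of `(x, y, z)` polyline vertices.
#' @return A `tube_spec` object.
#' @examples
#' sp <- tube_arc(centre = c(0, 0, 0), radius = 20, r = 3)
#' tube_truth(sp)$mean_curvature_per_um # 0.05
#' @export
tube_segment <- function(p0, p1, r) {
  stopifnot(length(p0) == 3, length(p1) == 3, r > 0)
  L <- sqrt(sum((p1 - p0)^2))
  if (L <= 0) stop("segment has zero length")
  structure(list(kind = "segment", p0 = as.numeric(p0), p1 = as.numeric(p1),
                 r = r), class = "tube_spec")
}

#' @rdname tube_segment
#' @export
tube_arc <- function(centre, radius, r, span = pi / 2, start_angle = 0,
                     plane = "xy") {
  stopifnot(length(centre) == 3, radius > 0, r > 0, span > 0)
  if (radius <= 2 * r)
    stop("arc radius must exceed 2 * tube radius (self-intersection)")
  plane <- match.arg(plane, c("xy", "xz", "yz"))
  structure(list(kind = "arc", centre = as.numeric(centre), R = radius,
                 r = r, span = span, start_angle = start_angle,
                 plane = plane), class = "tube_spec")
}

#' @rdname tube_segment
#' @export
tube_helix <- function(a, c_pitch, turns, r, centre = c(0, 0, 0)) {
  stopifnot(a > 0, turns > 0, r > 0)
  if (a <= 2 * r)
    stop("helix radius must exceed 2 * tube radius (self-intersection)")
  structure(list(kind = "helix", a = a, c_pitch = c_pitch, turns = turns,
                 r = r, centre = as.numeric(centre)), class = "tube_spec")
}

#' @rdname tube_segment
#' @export
tube_polyline <- function(points, r) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2, r > 0)
  L <- sum(sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2)))
  if (L <= 0) stop("polyline has zero length")
  structure(list(kind = "polyline", points = points, r = r),
            class = "tube_spec")
}

# plane basis vectors for arcs
arc_basis <- function(plane) {
  switch(plane,
         xy = list(e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
         xz = list(e1 = c(1, 0, 0), e2 = c(0, 0, 1)),
         yz = list(e1 = c(0, 1, 0), e2 = c(0, 0, 1)))
}

# dense (x, y, z) polyline sampling of a spec at roughly `step` um
spec_points <- function(spec, step) {
  switch(spec$kind,
    segment = {
      L <- sqrt(sum((spec$p1 - spec$p0)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(L / step) + 1L))
      cbind(spec$p0[1] + t * (spec$p1[1] - spec$p0[1]),
            spec$p0[2] + t * (spec$p1[2] - spec$p0[2]),
            spec$p0[3] + t * (spec$p1[3] - spec$p0[3]))
    },
    arc = {
      L <- spec$R * spec$span
      n <- max(3L, ceiling(L / step) + 1L)
      th <- seq(spec$start_angle, spec$start_angle + spec$span,
                length.out = n)
      b <- arc_basis(spec$plane)
      outer(rep(1, n), spec$centre) +
        spec$R * (cos(th) %o% b$e1 + sin(th) %o% b$e2)
    },
    helix = {
      tmax <- 2 * pi * spec$turns
      L <- tmax * sqrt(spec$a^2 + spec$c_pitch^2)
      n <- max(3L, ceiling(L / step) + 1L)
      t <- seq(0, tmax, length.out = n)
      cbind(spec$centre[1] + spec$a * cos(t),
            spec$centre[2] + spec$a * sin(t),
            spec$centre[3] + spec$c_pitch * t)
    },
    polyline = spec$points)
}

#' Analytic ground truth for a tube spec
#'
#' Volume is `pi r^2 L` and surface area the lateral area `2 pi r L`
#' (end caps excluded; a marching isosurface of the rasterized tube includes
#' caps, so comparisons must add `2 pi r^2`). Mean curvature is exact for
#' segments (0), arcs (`1/R`) and helices (`a/(a^2+c^2)`); for polylines it
#' is `NA`.
#'
#' @param spec A `tube_spec`.
#' @return A list of class `phantom_truth` with fields `length_um`,
#'   `mean_curvature_per_um`, `tube_radius_um`, `branch_count`,
#'   `volume_um3`, `surface_area_um2`.
#' @export
tube_truth <- function(spec) {
  L <- switch(spec$kind,
    segment = sqrt(sum((spec$p1 - spec$p0)^2)),
    arc = spec$R * spec$span,
    helix = 2 * pi * spec$turns * sqrt(spec$a^2 + spec$c_pitch^2),
    polyline = sum(sqrt(rowSums(diff(spec$points)^2))))
  kappa <- switch(spec$kind,
    segment = 0,
    arc = 1 / spec$R,
    helix = spec$a / (spec$a^2 + spec$c_pitch^2),
    polyline = NA_real_)
  structure(list(length_um = L, mean_curvature_per_um = kappa,
                 tube_radius_um = spec$r, branch_count = 0L,
                 volume_um3 = pi * spec$r^2 * L,
                 surface_area_um2 = 2 * pi * spec$r * L),
            class = "phantom_truth")
}

# fit a set of dense polylines (list of n x 3 matrices) into a fresh grid:
# shift so the tube (curve +/- r) starts `clear` voxels inside the grid
autofit_grid <- function(pt_list, r, spacing, clear = 2) {
  all_pts <- do.call(rbind, pt_list)
  lo <- apply(all_pts, 2, min) - r
  hi <- apply(all_pts, 2, max) + r
  margin <- clear * rev(spacing) # (x, y, z) margins
  # snap the shift to whole voxels: geometry given on lattice coordinates
  # then stays lattice-aligned. An axis-parallel tube centred exactly
  # between voxel rows has a two-voxel-wide medial set with no possible
  # curve endpoint, which every endpoint-preserving thinning (this one and
  # the classic published ones alike) retracts completely.
  shift <- ceiling((margin - lo) / rev(spacing)) * rev(spacing)
  extent <- hi + shift + margin # upper grid edge per (x, y, z) axis
  shape <- c(ceiling(extent[3] / spacing[1]) + 1L,
             ceiling(extent[2] / spacing[2]) + 1L,
             ceiling(extent[1] / spacing[3]) + 1L)
  list(shift = shift, shape = as.integer(shape))
}

check_fits <- function(pts, r, shape, spacing, clear = 2) {
  lo <- apply(pts, 2, min) - r
  hi <- apply(pts, 2, max) + r
  ext <- c((shape[3] - 1) * spacing[3], (shape[2] - 1) * spacing[2],
           (shape[1] - 1) * spacing[1])
  margin <- clear * rev(spacing)
  if (any(lo < margin - 1e-9) || any(hi > ext - margin + 1e-9))
    stop("tube exits grid (needs >= ", clear, " voxels clearance)")
}

#' Rasterize a tube phantom
#'
#' Voxels whose centre lies within `r` of the centreline become foreground
#' (crisp membership, no anti-aliasing; partial-volume effects are the
#' imaging model's job, see [render_acquisition()]).
#'
#' @param spec A `tube_spec`.
#' @param shape Grid dimensions `(nz, ny, nx)`, or `NULL` to auto-fit a grid
#'   around the tube (the geometry is then translated so it fits with two
#'   voxels of clearance).
#' @param spacing Voxel spacing `(dz, dy, dx)` micrometres.
#' @return A list with elements `mask` ([binary_mask()]) and `truth`
#'   ([tube_truth()]).
#' @examples
#' ph <- rasterize_tube(tube_segment(c(0,0,0), c(50,0,0), r = 3),
#'                      spacing = c(1, 1, 1))
#' ph$truth$volume_um3                       # 1413.72
#' sum(ph$mask$voxels)                       # close to the analytic volume
#' @export
rasterize_tube <- function(spec, shape = NULL, spacing = c(1, 1, 1)) {
  stopifnot(inherits(spec, "tube_spec"))
  step <- min(spacing) / 4
  pts <- spec_points(spec, step)
  if (spec$r < min(spacing))
    warning("tube radius ", spec$r, " um is below voxel spacing: ",
            "sub-resolution tube")
  if (is.null(shape)) {
    fit <- autofit_grid(list(pts), spec$r, spacing)
    pts <- sweep(pts, 2, fit$shift, `+`)
    shape <- fit$shape
  } else {
    shape <- as.integer(shape)
    check_fits(pts, spec$r, shape, spacing)
  }
  vox <- cpp_rasterize_tube(pts, spec$r, shape, spacing, c(0, 0, 0))
  mask <- binary_mask(array(vox, dim = shape), spacing)
  list(mask = mask, truth = tube_truth(spec))
}

#' Branching tree phantom
#'
#' A rooted tree of straight tube edges: `nodes` are `(x, y, z)` positions,
#' `parent[i]` is the index of node i's parent (`NA` for the root). The
#' ground-truth branch count is the number of nodes of graph degree >= 3.
#'
#' @param nodes n-by-3 matrix of node positions (micrometres).
#' @param parent Integer vector of parent indices (`NA` exactly once).
#' @param r Tube radius, scalar or one value per non-root node (edge).
#' @return A `tree_spec` object.
#' @export
tree_spec <- function(nodes, parent, r) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3, nrow(nodes) == length(parent))
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  n <- nrow(nodes)
  # walk to root from every node: detects cycles / disconnection
  for (i in seq_len(n)) {
    seen <- logical(n); j <- i
    while (!is.na(parent[j])) {
      if (seen[j]) stop("parent links contain a cycle")
      seen[j] <- TRUE
      j <- parent[j]
    }
  }
  deg <- tabulate(parent[!is.na(parent)], n) + as.integer(!is.na(parent))
  edges <- which(!is.na(parent))
  r <- rep_len(r, length(edges))
  structure(list(nodes = nodes, parent = as.integer(parent), r = r,
                 edges = edges, degree = deg,
                 branch_count = sum(deg >= 3L)), class = "tree_spec")
}

#' Rasterize a tree phantom
#'
#' Union of the straight tubes of all edges. Analytic volume/surface are the
#' per-edge sums (junction overlap makes them slight overestimates, noted in
#' the truth as `junction_overlap = TRUE`).
#'
#' @param spec A [tree_spec()].
#' @inheritParams rasterize_tube
#' @return A list `(mask, truth)`; `truth$branch_count` is the junction
#'   count of the tree, `truth$length_um` the summed edge length.
#' @export
rasterize_tree <- function(spec, shape = NULL, spacing = c(1, 1, 1)) {
  stopifnot(inherits(spec, "tree_spec"))
  seglist <- lapply(seq_along(spec$edges), function(k) {
    i <- spec$edges[k]
    rbind(spec$nodes[spec$parent[i], ], spec$nodes[i, ])
  })
  rmax <- max(spec$r)
  if (is.null(shape)) {
    fit <- autofit_grid(seglist, rmax, spacing)
    seglist <- lapply(seglist, function(s) sweep(s, 2, fit$shift, `+`))
    shape <- fit$shape
  } else {
    shape <- as.integer(shape)
    for (s in seglist) check_fits(s, rmax, shape, spacing)
  }
  vox <- NULL
  for (k in seq_along(seglist))
    vox <- cpp_rasterize_tube(seglist[[k]], spec$r[k], shape, spacing,
                              c(0, 0, 0), vox)
  lens <- vapply(seglist, function(s) sqrt(sum((s[2, ] - s[1, ])^2)), 0)
  truth <- structure(list(
    length_um = sum(lens), lengths_um = lens,
    mean_curvature_per_um = 0,
    tube_radius_um = mean(spec$r), branch_count = spec$branch_count,
    volume_um3 = sum(pi * spec$r^2 * lens),
    surface_area_um2 = sum(2 * pi * spec$r * lens),
    junction_overlap = TRUE), class = "phantom_truth")
  list(mask = binary_mask(array(vox, dim = shape), spacing), truth = truth)
}

#' Candelabra phantom
#'
#' Emulates the candelabra-like cascades of oxytalan fibres in young
#' papillary dermis: one arched base fibre running parallel to the top face
#' at `base_depth`, with `n_prongs` upward prongs reaching towards the
#' surface. Each prong attachment is one junction, so the ground-truth
#' branch count equals `n_prongs`.
#'
#' @param n_prongs Number of prongs (>= 2).
#' @param base_depth Depth (micrometres) of the base fibre below the top
#'   face.
#' @param prong_length Prong length in micrometres.
#' @param tube_radius Tube radius in micrometres.
#' @param jitter_sd SD (micrometres) of the lateral jitter applied to prong
#'   tips; 0 gives perfectly vertical prongs.
#' @param seed Integer seed (mandatory; generators are pure functions of
#'   parameters + seed).
#' @param base_span Base fibre extent along x in micrometres.
#' @param base_sag How much deeper (micrometres) the base arc is at its
#'   midpoint than at its ends.
#' @param spacing Voxel spacing `(dz, dy, dx)`.
#' @return A list `(mask, truth)` as for [rasterize_tree()].
#' @export
make_candelabra <- function(n_prongs, base_depth = 40, prong_length = 30,
                            tube_radius = 2, jitter_sd = 0, seed,
                            base_span = 60, base_sag = 6,
                            spacing = c(1, 1, 1)) {
  stopifnot(n_prongs >= 2, base_depth > 0, prong_length > 0, tube_radius > 0)
  if (missing(seed)) stop("`seed` is mandatory")
  geo <- with_local_seed(seed,
    candelabra_geometry(n_prongs, base_depth, prong_length, jitter_sd,
                        base_span, base_sag))
  fit <- autofit_grid(geo$seglist, tube_radius, spacing)
  seglist <- lapply(geo$seglist, function(s) sweep(s, 2, fit$shift, `+`))
  vox <- NULL
  for (s in seglist)
    vox <- cpp_rasterize_tube(s, tube_radius, fit$shape, spacing,
                              c(0, 0, 0), vox)
  total <- geo$base_len + sum(geo$prong_lens)
  truth <- structure(list(
    length_um = total, base_length_um = geo$base_len,
    prong_lengths_um = geo$prong_lens,
    mean_curvature_per_um = NA_real_,
    base_curvature_per_um = 1 / geo$Rb,
    tube_radius_um = tube_radius, branch_count = as.integer(n_prongs),
    volume_um3 = pi * tube_radius^2 * total,
    surface_area_um2 = 2 * pi * tube_radius * total,
    junction_overlap = TRUE), class = "phantom_truth")
  list(mask = binary_mask(array(vox, dim = fit$shape), spacing),
       truth = truth)
}

# candelabra geometry in um: one arched base fibre in the xz plane at depth
# base_depth (sagging by base_sag at mid-span), n_prongs prongs rising
# towards the surface from equally spaced attachment points, tips jittered
# laterally. Caller supplies the RNG state.
candelabra_geometry <- function(n_prongs, base_depth, prong_length,
                                jitter_sd, base_span, base_sag) {
  half <- base_span / 2
  Rb <- (half^2 + base_sag^2) / (2 * base_sag)
  cz <- base_depth + base_sag - Rb # circle centre z (above the base)
  th_half <- asin(half / Rb)
  nb <- max(31L, ceiling(2 * th_half * Rb))
  th <- seq(-th_half, th_half, length.out = nb)
  base_pts <- cbind(half + Rb * sin(th), 0, cz + Rb * cos(th))
  at_th <- seq(-th_half, th_half,
               length.out = n_prongs + 2L)[2:(n_prongs + 1L)]
  at <- cbind(half + Rb * sin(at_th), 0, cz + Rb * cos(at_th))
  prongs <- lapply(seq_len(n_prongs), function(i) {
    tip <- at[i, ] + c(rnorm(1, 0, jitter_sd), rnorm(1, 0, jitter_sd),
                       -prong_length)
    rbind(at[i, ], tip)
  })
  prong_lens <- vapply(prongs, function(pp) sqrt(sum((pp[2, ] - pp[1, ])^2)),
                       0)
  list(seglist = c(list(base_pts), prongs), base_len = 2 * th_half * Rb,
       prong_lens = prong_lens, Rb = Rb)
}

#' Synthetic dermal field phantom
#'
#' One candelabra (oxytalan-like, carrying the branch-count signal) plus
#' `n_arcs` long arched fibres running parallel to it at greater depth
#' (elaunin/elastic-like, carrying clean curvature and diameter signals) -
#' a minimal cartoon of the papillary dermis fibre population in one imaged
#' field.
#'
#' @inheritParams make_candelabra
#' @param arc_curvature Centreline curvature (1/um) of the arched fibres
#'   and of the candelabra base.
#' @param n_arcs Number of arched fibres (default 2).
#' @param arc_gap_um Depth spacing between consecutive arched fibres and
#'   the candelabra base (default 8; raised automatically to 4.5 x the tube
#'   radius so that thick fibres stay resolvable as separate objects).
#' @param arc_offset_um Lateral (y) offset between consecutive arched
#'   fibres (default 7, raised like `arc_gap_um`).
#' @return A list `(mask, truth)`; `truth$mean_curvature_per_um` is the arc
#'   curvature, `truth$branch_count = n_prongs`.
#' @export
make_field_phantom <- function(n_prongs, arc_curvature = 1 / 40,
                               base_depth = 30, prong_length = 22,
                               tube_radius = 2, jitter_sd = 0.5, seed,
                               base_span = 45, n_arcs = 3L, arc_gap_um = 8,
                               arc_offset_um = 7, spacing = c(1, 1, 1)) {
  stopifnot(n_prongs >= 2, arc_curvature > 0, tube_radius > 0)
  if (missing(seed)) stop("`seed` is mandatory")
  if (1 / arc_curvature <= 2 * tube_radius)
    stop("arc radius 1/curvature must exceed 2 * tube radius")
  arc_gap_um <- max(arc_gap_um, 4.5 * tube_radius)
  arc_offset_um <- max(arc_offset_um, 4.5 * tube_radius)
  R <- 1 / arc_curvature
  # strongly curved draws cannot span the full base width; shorten the arc
  # so it stays a sub-semicircular arch
  half <- min(base_span / 2, 0.85 * R)
  sag <- R - sqrt(max(R^2 - half^2, 0)) # same sag rule as the base
  geo <- with_local_seed(seed,
    candelabra_geometry(n_prongs, base_depth, prong_length, jitter_sd,
                        base_span, sag))
  th_half <- asin(half / R)
  th <- seq(-th_half, th_half, length.out = max(31L, ceiling(2 * th_half * R)))
  arcs <- lapply(seq_len(n_arcs), function(i) {
    depth <- base_depth + i * arc_gap_um
    yoff <- (i - (n_arcs + 1) / 2) * arc_offset_um
    cz <- depth + sag - R
    cbind(half + R * sin(th), yoff, cz + R * cos(th))
  })
  seglist <- c(geo$seglist, arcs)
  fit <- autofit_grid(seglist, tube_radius, spacing)
  seglist <- lapply(seglist, function(s) sweep(s, 2, fit$shift, `+`))
  vox <- NULL
  for (s in seglist)
    vox <- cpp_rasterize_tube(s, tube_radius, fit$shape, spacing,
                              c(0, 0, 0), vox)
  arc_len <- 2 * th_half * R
  total <- geo$base_len + sum(geo$prong_lens) + n_arcs * arc_len
  truth <- structure(list(
    length_um = total, mean_curvature_per_um = arc_curvature,
    tube_radius_um = tube_radius, branch_count = as.integer(n_prongs),
    volume_um3 = pi * tube_radius^2 * total,
    surface_area_um2 = 2 * pi * tube_radius * total,
    junction_overlap = TRUE), class = "phantom_truth")
  list(mask = binary_mask(array(vox, dim = fit$shape), spacing),
       truth = truth)
}
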