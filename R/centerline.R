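# Centreline refinement and resampling. Thinning yields voxel-quantized
# centrelines; each interior polyline point is replaced by the centre of
# gravity of the mask cross-section through it (plane normal to the local
# tangent), then the polyline is resampled at a fixed 1 um arc-length step
# so that curvature can be taken as a plain second difference.

# unit tangents of a polyline by central differences (one-sided at the ends)
path_tangents <- function(p) {
  n <- nrow(p)
  t <- matrix(0, n, 3)
  if (n == 2L) {
    t[1, ] <- t[2, ] <- p[2, ] - p[1, ]
  } else {
    t[1, ] <- p[2, ] - p[1, ]
    t[n, ] <- p[n, ] - p[n - 1, ]
    t[2:(n - 1), ] <- p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
  }
  nrm <- sqrt(rowSums(t^2))
  nrm[nrm == 0] <- 1
  t / nrm
}

# nearest-voxel inside test on the iso grid; pts are (x, y, z) um
inside_mask <- function(pts, mask_iso, h, depth_origin) {
  pts <- matrix(pts, ncol = 3)
  d <- dim(mask_iso)
  iz <- pmin(pmax(as.integer(round((pts[, 3] - depth_origin) / h)) + 1L, 1L),
             d[1])
  iy <- pmin(pmax(as.integer(round(pts[, 2] / h)) + 1L, 1L), d[2])
  ix <- pmin(pmax(as.integer(round(pts[, 1] / h)) + 1L, 1L), d[3])
  mask_iso[cbind(iz, iy, ix)]
}

# Shared cross-section machinery on the isotropic grid: nearest-voxel EDT
# lookup and the centre of gravity of the mask voxels in a one-voxel-thick
# slab normal to a given tangent, restricted to the local fibre extent
# (1.5 x the distance-transform value plus one voxel).
section_tools <- function(skel) {
  if (inherits(skel, "binary_mask")) {
    iso <- resample_isotropic(skel)
    skel <- structure(list(mask_iso = iso$voxels, spacing = iso$spacing,
                           depth_origin = skel$depth_origin),
                      class = "skeleton")
  }
  mask_iso <- skel$mask_iso
  h <- skel$spacing[1]
  dor <- skel$depth_origin
  d <- dim(mask_iso)
  edt <- array(cpp_edt(as.logical(mask_iso), d, skel$spacing), dim = d)
  vox_idx <- function(p) {
    c(pmin(pmax(as.integer(round((p[3] - dor) / h)) + 1L, 1L), d[1]),
      pmin(pmax(as.integer(round(p[2] / h)) + 1L, 1L), d[2]),
      pmin(pmax(as.integer(round(p[1] / h)) + 1L, 1L), d[3]))
  }
  list(
    skel = skel, h = h, dor = dor, mask_iso = mask_iso,
    edt_at = function(p) {
      i <- vox_idx(p)
      edt[i[1], i[2], i[3]]
    },
    inside = function(p) inside_mask(p, mask_iso, h, dor),
    cog = function(p, tang, r_fix = NULL) {
      i <- vox_idx(p)
      r_loc <- if (is.null(r_fix)) max(2 * h, 1.5 * edt[i[1], i[2], i[3]] + h)
               else max(2 * h, 1.5 * r_fix + h)
      rv <- ceiling(r_loc / h)
      zr <- max(1L, i[1] - rv):min(d[1], i[1] + rv)
      yr <- max(1L, i[2] - rv):min(d[2], i[2] + rv)
      xr <- max(1L, i[3] - rv):min(d[3], i[3] + rv)
      sub <- mask_iso[zr, yr, xr, drop = FALSE]
      w <- which(sub, arr.ind = TRUE)
      if (nrow(w) == 0L) return(NULL)
      vox <- cbind((xr[w[, 3]] - 1) * h, (yr[w[, 2]] - 1) * h,
                   dor + (zr[w[, 1]] - 1) * h)
      rel <- sweep(vox, 2, p)
      proj <- as.numeric(rel %*% tang)
      radial2 <- rowSums(rel^2) - proj^2
      # tent weight along the tangent: a hard +/- h/2 slab makes the CoG
      # jump as voxels cross the slab boundary; the tent varies smoothly,
      # and its 1.5-voxel half-width averages the staircase wiggle of
      # oblique thin fibres at its source
      wt <- pmax(0, 1 - abs(proj) / (1.5 * h))
      wt[radial2 > r_loc^2] <- 0
      if (sum(wt) <= 0) return(NULL)
      colSums(vox * wt) / sum(wt)
    })
}

#' Refine a centreline by cross-sectional centres of gravity
#'
#' Each interior polyline point is moved to the centre of gravity of the
#' mask voxels lying in a one-voxel-thick slab normal to the local tangent,
#' within the local fibre extent (1.5 x the distance-transform value plus
#' one voxel). Node positions are left untouched; points whose refined
#' position would leave the mask keep their previous position; points with
#' an empty cross-section are dropped with a warning.
#'
#' @param graph A `skeleton_graph`.
#' @param skel The `skeleton` the graph came from (supplies the isotropic
#'   mask), or a [binary_mask()] which is then resampled identically.
#' @param iterations Number of refinement sweeps (default 2; sweeps move
#'   points less and less, and the refinement is a fixed point on perfectly
#'   centred paths).
#' @return The refined `skeleton_graph`.
#' @export
refine_centerline <- function(graph, skel, iterations = 2L) {
  stopifnot(inherits(graph, "skeleton_graph"))
  st <- section_tools(skel)
  mask_iso <- st$mask_iso
  h <- st$h
  dor <- st$dor
  refine_point <- st$cog

  for (it in seq_len(iterations)) {
    for (ei in seq_along(graph$edges)) {
      p <- graph$edges[[ei]]$path
      n <- nrow(p)
      if (n <= 2L) next
      tang <- path_tangents(p)
      dropped <- logical(n)
      for (i in 2:(n - 1)) {
        q <- refine_point(p[i, ], tang[i, ])
        if (is.null(q)) {
          dropped[i] <- TRUE
          next
        }
        if (inside_mask(q, mask_iso, h, dor)) p[i, ] <- q
      }
      if (any(dropped)) {
        warning(sum(dropped), " centreline point(s) had an empty ",
                "cross-section and were dropped")
        p <- p[!dropped, , drop = FALSE]
      }
      graph$edges[[ei]]$path <- p
    }
  }
  graph
}

# Repair terminal edges at fibre ends. Thinning skeletons are unreliable
# within about one tube radius of an end cap: they retract and often hook
# towards the cap corners. For every free (endpoint) edge end the distorted
# cap zone (1.5 x the local radius, from the distance transform) is trimmed
# off, and the path is then regrown in half-voxel steps, each step
# re-centred on the cross-sectional centre of gravity so the regrowth
# follows curved axes, until the centreline reaches the mask boundary.
extend_tips <- function(graph, skel, trim_factor = 1.5) {
  st <- section_tools(skel)
  h <- st$h
  deg <- node_degrees(graph)
  for (ei in seq_along(graph$edges)) {
    e <- graph$edges[[ei]]
    for (side in c("from", "to")) {
      nid <- e[[side]]
      krow <- graph$nodes$kind[graph$nodes$id == nid]
      if (!length(krow) || krow != "endpoint" ||
          deg[as.character(nid)] != 1L) next
      p <- graph$edges[[ei]]$path
      if (side == "from") p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      trim_um <- trim_factor *
        stats::median(apply(p, 1, st$edt_at))
      total <- polyline_length(p)
      if (total > 3 * trim_um && nrow(p) > 4L) {
        # drop trailing points inside the cap zone
        seg <- sqrt(rowSums(diff(p)^2))
        from_end <- rev(cumsum(rev(seg)))
        keep_n <- max(3L, sum(from_end > trim_um) + 1L)
        p <- p[seq_len(min(keep_n, nrow(p))), , drop = FALSE]
      }
      # regrow by open-loop extrapolation of a local quadratic fit in arc
      # length: follows the fibre's curvature out to the boundary but cannot
      # spiral along the cap face the way tangent-following feedback can
      n <- nrow(p)
      m <- min(7L, n)
      tailp <- p[(n - m + 1L):n, , drop = FALSE]
      s <- c(0, cumsum(sqrt(rowSums(diff(tailp)^2))))
      degfit <- if (m >= 5L) 2L else 1L
      X <- outer(s, 0:degfit, `^`)
      beta <- qr.solve(X, tailp) # 3 coordinate polynomials
      s_end <- s[length(s)]
      grown <- 0
      limit <- trim_um + 3 * h
      repeat {
        if (grown + h / 2 > limit) break
        s_new <- s_end + grown + h / 2
        cand <- as.numeric(t(beta) %*% (s_new^(0:degfit)))
        if (!st$inside(cand)) break
        p <- rbind(p, cand)
        grown <- grown + h / 2
      }
      if (side == "from") p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      graph$edges[[ei]]$path <- p
      tip <- if (side == "from") p[1, ] else p[nrow(p), ]
      graph$nodes[graph$nodes$id == nid, c("x", "y", "z")] <- as.list(tip)
    }
  }
  graph
}

#' Resample a polyline at fixed arc length
#'
#' Linear interpolation along the polyline at cumulative arc lengths
#' `0, step, 2 step, ...`; the original endpoint is always kept, so the last
#' interval may be shorter than `step`. A 1 um step makes the second
#' difference of the points a direct curvature estimate.
#'
#' @param polyline n-by-3 matrix of ordered `(x, y, z)` micrometre points.
#' @param step_um Arc-length step (default 1.0).
#' @return A `fibre_path`: matrix of resampled points with attributes
#'   `step_um` and `length_um`.
#' @examples
#' p <- cbind(seq(0, 10.4, length.out = 53), 0, 0)
#' nrow(resample_arclength(p)) # 12 points, final interval 0.4 um
#' @export
resample_arclength <- function(polyline, step_um = 1.0) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 3, step_um > 0)
  seg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                         polyline[-nrow(polyline), , drop = FALSE])^2))
  L <- sum(seg)
  if (nrow(polyline) < 2L || L <= 0)
    stop("cannot resample a zero-length polyline")
  cum <- c(0, cumsum(seg))
  s <- seq(0, L, by = step_um)
  if (L - s[length(s)] > 1e-9) s <- c(s, L)
  out <- cbind(approx(cum, polyline[, 1], xout = s, ties = "ordered")$y,
               approx(cum, polyline[, 2], xout = s, ties = "ordered")$y,
               approx(cum, polyline[, 3], xout = s, ties = "ordered")$y)
  out[1, ] <- polyline[1, ]
  out[nrow(out), ] <- polyline[nrow(polyline), ]
  structure(out, step_um = step_um, length_um = L, class = "fibre_path")
}

#' Smooth a fibre path
#'
#' Moving average of the coordinates with reflective end handling; the two
#' endpoints are preserved exactly and `window = 1` is the identity. Tames
#' residual voxel jitter before second differences are taken.
#'
#' @param path A `fibre_path` (or plain n-by-3 matrix).
#' @param window Odd window length (default 5).
#' @return The smoothed path (attributes preserved).
#' @export
smooth_path <- function(path, window = 5L) {
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (window == 1L) return(path)
  p <- unclass(path)
  n <- nrow(p)
  if (n < 3L) return(path)
  half <- (window - 1L) %/% 2L
  # no end padding: near the ends the window shrinks symmetrically
  # (window 1 at the endpoints themselves). Any symmetric moving average
  # preserves straight lines exactly, and shrinking avoids the curvature
  # bias that reflective or extrapolated padding introduces on curved paths
  out <- p
  cs <- rbind(0, apply(p, 2, cumsum))
  for (i in seq_len(n)) {
    hw <- min(half, i - 1L, n - i)
    out[i, ] <- (cs[i + hw + 1L, ] - cs[i - hw, ]) / (2L * hw + 1L)
  }
  attributes(out) <- attributes(path)
  attr(out, "end_affected") <- half # truncated-window points at each end
  out
}

#' Serialize a skeleton graph
#'
#' `graph_to_json()` writes nodes, edges and polylines (micrometres) as
#' JSON; `graph_to_swc()` writes an SWC-like point/parent table usable by
#' neuron-morphology viewers (type 0, radius 1).
#'
#' @param graph A `skeleton_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
graph_to_json <- function(graph, path) {
  obj <- list(
    spacing = graph$spacing, depth_origin = graph$depth_origin,
    nodes = graph$nodes,
    edges = lapply(graph$edges, function(e)
      list(id = e$id, from = e$from, to = e$to,
           path = unname(as.matrix(e$path)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname graph_to_json
#' @export
graph_to_swc <- function(graph, path) {
  rows <- character()
  counter <- 0L
  node_swc <- integer(0) # node id -> swc index
  for (e in graph$edges) {
    p <- e$path
    parent <- if (as.character(e$from) %in% names(node_swc))
      node_swc[[as.character(e$from)]] else -1L
    start <- if (parent > 0L) 2L else 1L
    for (i in start:nrow(p)) {
      counter <- counter + 1L
      rows <- c(rows, sprintf("%d 0 %.6f %.6f %.6f 1.0 %d", counter,
                              p[i, 1], p[i, 2], p[i, 3], parent))
      if (i == 1L) node_swc[[as.character(e$from)]] <- counter
      if (i == nrow(p)) node_swc[[as.character(e$to)]] <- counter
      parent <- counter
    }
  }
  writeLines(c("# SWC-like export: index type x y z radius parent", rows),
             path)
  invisible(path)
}
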