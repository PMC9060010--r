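# Skeletonization and the skeleton graph. The mask is resampled to an
# isotropic grid (3D thinning assumes isotropy), thinned to a one-voxel
# curve skeleton by homotopic thinning, then parsed into a spatial graph of
# endpoint/junction nodes and polyline edges in physical micrometres.

#' Skeletonize a binary mask
#'
#' Nearest-neighbour resampling to an isotropic working grid at
#' `min(spacing)`, followed by topology-preserving (homotopic) 3D thinning:
#' only simple points are ever removed, so the connected-component count of
#' the skeleton equals that of the mask.
#'
#' @param mask A [binary_mask()].
#' @return A list of class `skeleton`: `voxels` (logical iso-grid array),
#'   `mask_iso` (the resampled mask, used by centreline refinement),
#'   `spacing` (isotropic, length 3), `depth_origin`.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("cannot skeletonize an empty mask")
  iso <- resample_isotropic(mask)
  d <- dim(iso$voxels)
  sk <- cpp_thin3d(as.logical(iso$voxels), d)
  structure(list(voxels = array(sk, dim = d), mask_iso = iso$voxels,
                 spacing = iso$spacing, depth_origin = mask$depth_origin),
            class = "skeleton")
}

# nearest-neighbour resampling of a mask to an isotropic grid at min(spacing)
resample_isotropic <- function(mask) {
  d <- dim(mask$voxels)
  h <- min(mask$spacing)
  if (all(abs(mask$spacing - h) < 1e-12))
    return(list(voxels = mask$voxels, spacing = rep(h, 3)))
  n_iso <- pmax(1L, as.integer(round((d - 1L) * mask$spacing / h)) + 1L)
  idx <- lapply(1:3, function(ax) {
    pos <- (seq_len(n_iso[ax]) - 1) * h
    pmin(pmax(as.integer(round(pos / mask$spacing[ax])) + 1L, 1L), d[ax])
  })
  list(voxels = mask$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
       spacing = rep(h, 3))
}

# (x, y, z) um coordinates of 1-based (z, y, x) voxel indices on the iso grid
skel_um <- function(idx_zyx, h, depth_origin) {
  idx_zyx <- matrix(idx_zyx, ncol = 3)
  cbind((idx_zyx[, 3] - 1) * h, (idx_zyx[, 2] - 1) * h,
        depth_origin + (idx_zyx[, 1] - 1) * h)
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

new_graph <- function(nodes, edges, spacing, depth_origin) {
  structure(list(nodes = nodes, edges = edges, spacing = spacing,
                 depth_origin = depth_origin), class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind,
                        levels = c("endpoint", "junction", "isolated")))
  cat(sprintf(paste0("<skeleton_graph> %d nodes (%d endpoints, %d junctions,",
                     " %d isolated), %d edges\n"),
              nrow(x$nodes), kinds[1], kinds[2], kinds[3], length(x$edges)))
  invisible(x)
}

node_degrees <- function(graph) {
  deg <- setNames(rep(0L, nrow(graph$nodes)), graph$nodes$id)
  for (e in graph$edges) {
    deg[as.character(e$from)] <- deg[as.character(e$from)] + 1L
    deg[as.character(e$to)] <- deg[as.character(e$to)] + 1L
  }
  deg
}

#' Build the skeleton graph
#'
#' Skeleton voxels are classified by their 26-neighbour count (1 gives an
#' endpoint, 3 or more a junction candidate); 26-connected clusters of
#' junction candidates are merged into a single junction node at their
#' centroid (thick crossings otherwise double-count). Chains of degree-2
#' voxels become polyline edges; closed loops without any node get one
#' anchor node of kind `"isolated"`.
#'
#' @param skel A `skeleton` from [skeletonize()].
#' @return A `skeleton_graph`: `nodes` data frame
#'   (`id`, `x`, `y`, `z`, `kind`) and `edges` list
#'   (`id`, `from`, `to`, `path` n-by-3 matrix, micrometres).
#' @export
build_graph <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  d <- dim(skel$voxels)
  h <- skel$spacing[1]
  lin <- which(skel$voxels)
  if (length(lin) == 0L) stop("empty skeleton")
  counts <- cpp_neighbor_counts(as.logical(skel$voxels), d)[lin]
  zyx <- cbind((lin - 1L) %% d[1] + 1L,
               ((lin - 1L) %/% d[1]) %% d[2] + 1L,
               (lin - 1L) %/% (d[1] * d[2]) + 1L)
  um <- skel_um(zyx, h, skel$depth_origin)
  pos_of <- setNames(seq_along(lin), lin) # linear index -> row

  pairs <- cpp_adjacency_pairs(as.logical(skel$voxels), d)
  pa <- pos_of[as.character(pairs[, 1])]
  pb <- pos_of[as.character(pairs[, 2])]

  is_cand <- counts >= 3L
  # adjacency lists over skeleton voxels
  adj <- vector("list", length(lin))
  if (length(pa)) {
    for (k in seq_along(pa)) {
      adj[[pa[k]]] <- c(adj[[pa[k]]], pb[k])
      adj[[pb[k]]] <- c(adj[[pb[k]]], pa[k])
    }
  }

  # merge 26-connected junction candidates into clusters
  cluster <- rep(NA_integer_, length(lin))
  ncl <- 0L
  for (v in which(is_cand)) {
    if (!is.na(cluster[v])) next
    ncl <- ncl + 1L
    queue <- v
    cluster[v] <- ncl
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[cur]]) {
        if (is_cand[w] && is.na(cluster[w])) {
          cluster[w] <- ncl
          queue <- c(queue, w)
        }
      }
    }
  }

  nodes <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), kind = character(),
                      stringsAsFactors = FALSE)
  next_id <- 0L
  add_node <- function(xyz, kind) {
    next_id <<- next_id + 1L
    nodes[nrow(nodes) + 1L, ] <<- list(next_id, xyz[1], xyz[2], xyz[3], kind)
    next_id
  }
  cl_node <- integer(ncl)
  for (cl in seq_len(ncl)) {
    members <- which(cluster == cl)
    cl_node[cl] <- add_node(colMeans(um[members, , drop = FALSE]), "junction")
  }

  # chain voxels (degree <= 2): connected chains are paths or cycles
  is_chain <- !is_cand
  chain_seen <- rep(FALSE, length(lin))
  edges <- list()
  next_eid <- 0L
  add_edge <- function(from, to, path) {
    next_eid <<- next_eid + 1L
    edges[[next_eid]] <<- list(id = next_eid, from = from, to = to,
                               path = path)
  }
  # map voxel -> endpoint node id (created lazily)
  ep_node <- rep(NA_integer_, length(lin))
  endpoint_of <- function(v) {
    if (is.na(ep_node[v])) ep_node[v] <<- add_node(um[v, ], "endpoint")
    ep_node[v]
  }
  adj_clusters <- function(v) unique(cluster[adj[[v]][is_cand[adj[[v]]]]])

  for (v0 in which(is_chain)) {
    if (chain_seen[v0]) next
    if (length(adj[[v0]]) == 0L) { # isolated voxel: node added below
      chain_seen[v0] <- TRUE
      next
    }
    # walk to one end of the chain (or detect a cycle)
    walk <- function(start) {
      path <- start
      chain_seen[start] <<- TRUE
      repeat {
        nxt <- setdiff(adj[[path[length(path)]]][
          is_chain[adj[[path[length(path)]]]]], path)
        # keep only unvisited chain neighbours
        nxt <- nxt[!chain_seen[nxt]]
        if (!length(nxt)) break
        nxt <- nxt[1]
        chain_seen[nxt] <<- TRUE
        path <- c(path, nxt)
      }
      path
    }
    # find a terminal of this chain component first
    comp <- walk(v0)
    # v0 may be mid-chain: extend backwards
    back <- setdiff(adj[[v0]][is_chain[adj[[v0]]]], comp)
    back <- back[!chain_seen[back]]
    if (length(back)) {
      comp2 <- walk(back[1])
      comp <- c(rev(comp2), comp)
    }
    first <- comp[1]; last <- comp[length(comp)]
    cyc <- length(comp) > 2L && last %in% adj[[first]] &&
      !length(adj_clusters(first)) && !length(adj_clusters(last))
    if (cyc) {
      anchor <- add_node(um[first, ], "isolated")
      path <- rbind(um[comp, , drop = FALSE], um[first, ])
      add_edge(anchor, anchor, path)
      next
    }
    cl_a <- adj_clusters(first)
    cl_b <- adj_clusters(last)
    if (length(comp) == 1L && length(cl_a) >= 2L) {
      # single voxel bridging two clusters
      cl_b <- cl_a[2]; cl_a <- cl_a[1]
    } else {
      cl_a <- if (length(cl_a)) cl_a[1] else NA_integer_
      cl_b <- if (length(cl_b)) cl_b[1] else NA_integer_
      if (length(comp) == 1L) cl_b <- NA_integer_
    }
    from <- if (!is.na(cl_a)) cl_node[cl_a] else endpoint_of(first)
    to <- if (!is.na(cl_b)) cl_node[cl_b] else endpoint_of(last)
    path <- um[comp, , drop = FALSE]
    if (!is.na(cl_a))
      path <- rbind(as.numeric(nodes[nodes$id == from, c("x", "y", "z")]),
                    path)
    if (!is.na(cl_b))
      path <- rbind(path,
                    as.numeric(nodes[nodes$id == to, c("x", "y", "z")]))
    if (nrow(path) < 2L) next # isolated single voxel handled below
    add_edge(from, to, path)
  }

  # isolated voxels (no neighbours at all)
  for (v in which(counts == 0L))
    add_node(um[v, ], "isolated")

  # clusters with no incident edges (blob collapsed to a junction-like knot)
  g <- new_graph(nodes, edges, skel$spacing, skel$depth_origin)
  deg <- node_degrees(g)
  g$nodes$kind[g$nodes$kind == "junction" &
                 deg[as.character(g$nodes$id)] == 0L] <- "isolated"
  # junction clusters that ended up with degree <= 2 are not true branchings
  g$nodes$kind[g$nodes$kind == "junction" &
                 deg[as.character(g$nodes$id)] == 1L] <- "endpoint"
  g
}

#' Prune skeletonization spurs
#'
#' Short terminal edges (default < 3 um) emanating from junctions are
#' thinning artefacts on thick fibres and inflate the branch count; they are
#' removed, after which junctions left with exactly two incident edges are
#' dissolved (their edges merged into one polyline).
#'
#' @param graph A `skeleton_graph`.
#' @param min_length_um Prune threshold in micrometres (default 3).
#' @return The pruned `skeleton_graph`.
#' @export
prune_spurs <- function(graph, min_length_um = 3) {
  repeat {
    deg <- node_degrees(graph)
    kind <- setNames(graph$nodes$kind, graph$nodes$id)
    drop <- integer()
    for (e in graph$edges) {
      if (polyline_length(e$path) >= min_length_um) next
      kf <- kind[as.character(e$from)]; kt <- kind[as.character(e$to)]
      df <- deg[as.character(e$from)]; dt <- deg[as.character(e$to)]
      # spur: one side a leaf (endpoint, degree 1), other side a junction
      if ((kf == "endpoint" && df == 1L && kt == "junction") ||
          (kt == "endpoint" && dt == 1L && kf == "junction"))
        drop <- c(drop, e$id)
    }
    if (!length(drop)) break
    graph$edges <- Filter(function(e) !(e$id %in% drop), graph$edges)
    graph <- dissolve_degree2(graph)
    # drop nodes that lost all edges
    deg <- node_degrees(graph)
    keep <- deg[as.character(graph$nodes$id)] > 0L |
      graph$nodes$kind == "isolated"
    graph$nodes <- graph$nodes[keep, , drop = FALSE]
  }
  graph
}

# merge the two edges of every degree-2 junction node into one polyline and
# reclassify junctions of degree 1 as endpoints
dissolve_degree2 <- function(graph) {
  repeat {
    deg <- node_degrees(graph)
    jid <- graph$nodes$id[graph$nodes$kind == "junction" &
                            deg[as.character(graph$nodes$id)] == 2L]
    if (!length(jid)) break
    n <- jid[1]
    inc <- Filter(function(e) (e$from == n) != (e$to == n), graph$edges)
    if (length(inc) < 2L) { # self-loop at n: leave as is
      graph$nodes$kind[graph$nodes$id == n] <- "isolated"
      next
    }
    e1 <- inc[[1]]; e2 <- inc[[2]]
    p1 <- if (e1$to == n) e1$path else e1$path[rev(seq_len(nrow(e1$path))), ,
                                              drop = FALSE]
    a <- if (e1$to == n) e1$from else e1$to
    p2 <- if (e2$from == n) e2$path else e2$path[rev(seq_len(nrow(e2$path))), ,
                                                drop = FALSE]
    b <- if (e2$from == n) e2$to else e2$from
    merged <- list(id = e1$id, from = a, to = b,
                   path = rbind(p1, p2[-1, , drop = FALSE]))
    graph$edges <- Filter(function(e) !(e$id %in% c(e1$id, e2$id)),
                          graph$edges)
    graph$edges[[length(graph$edges) + 1L]] <- merged
    graph$nodes <- graph$nodes[graph$nodes$id != n, , drop = FALSE]
  }
  deg <- node_degrees(graph)
  graph$nodes$kind[graph$nodes$kind == "junction" &
                     deg[as.character(graph$nodes$id)] == 1L] <- "endpoint"
  graph
}

#' Count fibre branches
#'
#' The number of junction nodes of the (spur-pruned) skeleton graph.
#'
#' @param graph A `skeleton_graph`.
#' @return Integer branch count.
#' @export
branch_count <- function(graph) {
  stopifnot(inherits(graph, "skeleton_graph"))
  sum(graph$nodes$kind == "junction")
}
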