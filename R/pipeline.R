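# End-to-end field analysis: depth crop -> preprocess -> binarize ->
# speckle removal -> skeletonize -> graph -> spur pruning -> centre-of-
# gravity refinement -> 1 um resampling -> per-fibre and field metrics.

#' Default analysis configuration
#'
#' All tunable parameters of [analyze_field()] with their defaults; unknown
#' keys passed in `...` or via [analyze_field()]'s `config` are rejected, so
#' typos cannot silently fall back to defaults.
#'
#' @param ... Overrides, e.g. `default_config(max_depth_um = 80)` or nested
#'   `default_config(segmentation = list(method = 0.5))`.
#' @return A named list of class `fm_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    max_depth_um = 100,
    fibre_channel = "tropoelastin",
    ratio_channels = c("fibrillin1", "tropoelastin"), # numerator, denominator
    segmentation = list(
      method = "otsu",          # or a fixed numeric threshold
      smooth_sigma_um = c(0.5, 0.5, 0.5),
      background_radius_um = NULL,
      min_volume_um3 = 10,
      connectivity = 26L,
      per_slice = FALSE         # per-slice Otsu for strongly attenuated stacks
    ),
    centerline = list(
      step_um = 1.0,
      prune_um = 3,
      smooth_window = 7L,
      refine_iterations = 2L,
      extend_tips = TRUE
    ),
    morphometry = list(
      junction_exclusion_um = 2,
      curvature_mode = "per_fibre", # or "pooled"
      diameter_method = "section",  # or "edt"
      surface_smooth_sigma_vox = 0.8,
      min_fibre_length_um = 2,
      min_curvature_points = 10L    # fewer usable points: curvature NA
    )
  )
  apply_overrides(cfg, list(...), "config")
}

apply_overrides <- function(base, over, where) {
  if (!length(over)) return(structure(base, class = "fm_config"))
  bad <- setdiff(names(over), names(base))
  if (length(bad))
    stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- apply_overrides(base[[nm]], over[[nm]],
                                    paste0(where, "$", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  structure(base, class = "fm_config")
}

empty_field_metrics <- function(cfg, threshold = NA_real_) {
  structure(list(volume_fraction = 0, surface_area_um2 = 0,
                 n_branches = 0L, n_fibres = 0L,
                 lengths_um = numeric(0), diameters_um = numeric(0),
                 curvatures_per_um = numeric(0),
                 intensity_ratio = NA_real_, empty = TRUE,
                 threshold = threshold, config = cfg),
            class = "field_metrics")
}

#' Analyse one image stack
#'
#' Runs the full measurement pipeline on the fibre channel of a stack and
#' returns field metrics plus per-fibre values. Deterministic for a fixed
#' input and configuration. Each skeleton-graph edge is one fibre; points
#' within `junction_exclusion_um` of a junction are excluded from diameter
#' and curvature averaging (cross-sections there span several fibres).
#'
#' @param stack An [image_stack()] containing the configured fibre channel.
#' @param config A [default_config()] (or overrides list).
#' @return A `field_metrics` list: `volume_fraction`, `surface_area_um2`,
#'   `n_branches`, `n_fibres`, `lengths_um`, `diameters_um`,
#'   `curvatures_per_um`, `intensity_ratio` (`NA` unless both ratio
#'   channels are present), `empty` flag, the applied `threshold`, the
#'   resolved `config`, and the `graph`.
#' @export
analyze_field <- function(stack, config = default_config()) {
  stopifnot(inherits(stack, "image_stack"))
  if (!inherits(config, "fm_config"))
    config <- apply_overrides(unclass(default_config()), config, "config")
  cfg <- config
  if (!cfg$fibre_channel %in% stack$channels)
    stop("stack has no '", cfg$fibre_channel, "' channel")

  stack <- crop_to_depth(stack, cfg$max_depth_um)
  ch <- stack$voxels[[cfg$fibre_channel]]
  ch <- preprocess(ch, stack$spacing,
                   smooth_sigma_um = cfg$segmentation$smooth_sigma_um,
                   background_radius_um = cfg$segmentation$background_radius_um)
  if (isTRUE(cfg$segmentation$per_slice) &&
      identical(cfg$segmentation$method, "otsu")) {
    # per-slice Otsu for strongly depth-attenuated stacks; slices without
    # contrast stay background
    vox <- array(FALSE, dim(ch))
    thr <- rep(NA_real_, dim(ch)[1])
    for (z in seq_len(dim(ch)[1])) {
      sl <- ch[z, , ]
      if (length(unique(as.numeric(sl))) < 2L) next
      thr[z] <- otsu_threshold(sl)
      vox[z, , ] <- sl > thr[z]
    }
    mask <- binary_mask(vox, stack$spacing, stack$depth_origin)
    attr(mask, "threshold") <- thr
  } else {
    mask <- binarize(ch, stack$spacing, method = cfg$segmentation$method,
                     depth_origin = stack$depth_origin)
  }
  thr <- attr(mask, "threshold")
  mask <- remove_small_components(mask, cfg$segmentation$min_volume_um3,
                                  cfg$segmentation$connectivity)
  if (!any(mask$voxels)) return(empty_field_metrics(cfg, thr))

  skel <- skeletonize(mask)
  graph <- build_graph(skel)
  graph <- prune_spurs(graph, cfg$centerline$prune_um)
  graph <- refine_centerline(graph, skel, cfg$centerline$refine_iterations)
  if (isTRUE(cfg$centerline$extend_tips)) {
    graph <- extend_tips(graph, skel)
    # pull the straight tip extensions back onto curved axes
    graph <- refine_centerline(graph, skel, 1L)
  }

  junctions <- graph$nodes[graph$nodes$kind == "junction", c("x", "y", "z")]
  st <- section_tools(skel)
  lengths <- diameters <- curvatures <- numeric(0)
  npts <- integer(0)
  for (e in graph$edges) {
    L <- polyline_length(e$path)
    if (L < cfg$morphometry$min_fibre_length_um) next
    fp <- resample_arclength(e$path, cfg$centerline$step_um)
    fp <- smooth_path(fp, cfg$centerline$smooth_window)
    # junction exclusion zone grows with the fibre's own radius: the
    # centreline is distorted for about one tube radius around a junction
    r_edge <- stats::median(apply(unclass(fp), 1, st$edt_at))
    jx <- max(cfg$morphometry$junction_exclusion_um, 1.5 * r_edge + 1)
    keep <- rep(TRUE, nrow(fp))
    if (nrow(junctions) > 0 && jx > 0) {
      for (j in seq_len(nrow(junctions))) {
        dj <- sqrt((fp[, 1] - junctions$x[j])^2 +
                     (fp[, 2] - junctions$y[j])^2 +
                     (fp[, 3] - junctions$z[j])^2)
        keep <- keep & dj > jx
      }
    }
    lengths <- c(lengths, fibre_length(fp))
    # curvature needs enough usable points: on stubs between junctions the
    # few samples that survive the exclusion zones sit right at the kink
    # boundary, so their second differences are all artefact; leave such
    # fibres' curvature undefined rather than report noise
    kap <- if (sum(keep) >= cfg$morphometry$min_curvature_points)
      fibre_curvature(fp, keep = keep) else NA_real_
    curvatures <- c(curvatures, kap)
    dia <- tryCatch(
      fibre_diameter(fp, skel, method = cfg$morphometry$diameter_method,
                     keep = if (any(keep)) keep else NULL),
      error = function(e) NA_real_)
    diameters <- c(diameters, dia)
    npts <- c(npts, nrow(fp))
  }

  ratio <- NA_real_
  rc <- cfg$ratio_channels
  if (all(rc %in% stack$channels))
    ratio <- channel_intensity_ratio(mask, stack$voxels[[rc[1]]],
                                     stack$voxels[[rc[2]]])

  structure(list(
    volume_fraction = volume_fraction(mask),
    surface_area_um2 = surface_area(
      mask, cfg$morphometry$surface_smooth_sigma_vox),
    n_branches = branch_count(graph),
    n_fibres = length(lengths),
    lengths_um = lengths, diameters_um = diameters,
    curvatures_per_um = curvatures, n_points = npts,
    intensity_ratio = ratio, empty = FALSE, threshold = thr,
    config = cfg, graph = graph), class = "field_metrics")
}

#' @export
print.field_metrics <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<field_metrics> empty field (no foreground after segmentation)\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("<field_metrics> %d fibre(s), %d branch(es)\n",
           "  volume fraction %.4f, surface area %.1f um^2\n",
           "  mean length %.2f um, mean diameter %.2f um, ",
           "mean curvature %.4f 1/um\n"),
    x$n_fibres, x$n_branches, x$volume_fraction, x$surface_area_um2,
    mean(x$lengths_um), mean(x$diameters_um, na.rm = TRUE),
    field_curvature(x)))
  if (!is.na(x$intensity_ratio))
    cat(sprintf("  fibrillin-1 / tropoelastin intensity ratio %.3f\n",
                x$intensity_ratio))
  invisible(x)
}

#' Field-level mean curvature
#'
#' Fibre curvatures averaged per fibre and then across fibres (the default),
#' or pooled over all sampled points via length weighting
#' (`mode = "pooled"`).
#'
#' @param field A `field_metrics` object.
#' @param mode `"per_fibre"` or `"pooled"`.
#' @return Mean curvature in 1/um (`NA` when undefined for every fibre).
#' @export
field_curvature <- function(field, mode = NULL) {
  mode <- mode %||% field$config$morphometry$curvature_mode
  k <- field$curvatures_per_um
  ok <- !is.na(k)
  if (!any(ok)) return(NA_real_)
  if (mode == "pooled") {
    w <- field$n_points[ok]
    sum(k[ok] * w) / sum(w)
  } else {
    mean(k[ok])
  }
}

#' Per-fibre metric table
#'
#' @param field A `field_metrics` object.
#' @return `data.frame` with `fibre_id`, `length_um`, `mean_diameter_um`,
#'   `mean_curvature_per_um`, `n_points`.
#' @export
fibre_table <- function(field) {
  data.frame(fibre_id = seq_len(field$n_fibres),
             length_um = field$lengths_um,
             mean_diameter_um = field$diameters_um,
             mean_curvature_per_um = field$curvatures_per_um,
             n_points = if (length(field$n_points)) field$n_points
                        else integer(0))
}

#' Summarise a field as a metrics record
#'
#' @param field A `field_metrics` object.
#' @param sample_id,group,site Identifiers for the record.
#' @return A one-row `data.frame` (see [metrics_record()]); metrics that are
#'   undefined for the field stay `NA`.
#' @export
field_to_record <- function(field, sample_id, group = NA_character_,
                            site = NA_character_) {
  mean_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  rec <- metrics_record(sample_id, group, site,
                        volume_fraction = field$volume_fraction,
                        surface_area_um2 = field$surface_area_um2,
                        n_branches = field$n_branches,
                        n_fibres = field$n_fibres,
                        mean_length_um = mean_or_na(field$lengths_um),
                        mean_diameter_um = mean_or_na(field$diameters_um))
  rec$mean_curvature_per_um <- field_curvature(field)
  rec$intensity_ratio <- field$intensity_ratio
  rec
}
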