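#' Read a multichannel Z-stack from a multipage TIFF
#'
#' Reads an uncompressed multipage (OME-style) TIFF into an [image_stack()].
#' Page layout (`ZCYX` or `CZYX`) and acquisition metadata are taken from the
#' JSON ImageDescription written by [write_stack()]; when that is absent a
#' JSON sidecar `<path>.json` (fields `spacing`, `channels`, `axes`,
#' `depth_origin`) is consulted. Channel roles always come from the caller or
#' the sidecar, never guessed from staining metadata.
#'
#' @param path TIFF file path.
#' @param spacing_override Optional `(dz, dy, dx)` in micrometres; when
#'   given it wins over any stored spacing (a message records this).
#' @param channel_roles Optional ordered channel role labels; must match the
#'   stored channel count.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, spacing_override = NULL, channel_roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tf <- read_tiff_pages(path)
  meta <- NULL
  if (!is.null(tf$desc))
    meta <- tryCatch(jsonlite::fromJSON(tf$desc), error = function(e) NULL)
  sidecar <- paste0(path, ".json")
  if (is.null(meta) && file.exists(sidecar))
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)

  npages <- length(tf$pages)
  channels <- meta$channels
  if (!is.null(channel_roles)) {
    nc <- length(channel_roles)
    if (!is.null(channels) && length(channels) != nc)
      stop("channel count mismatch: file stores ", length(channels),
           " channels but ", nc, " roles were given")
    if (npages %% nc != 0L)
      stop("channel count mismatch: ", npages,
           " pages are not divisible by ", nc, " channels")
    channels <- as.character(channel_roles)
  }
  if (is.null(channels)) stop("channel roles unavailable: pass `channel_roles`")
  nc <- length(channels)
  if (npages %% nc != 0L)
    stop("channel count mismatch: ", npages, " pages, ", nc, " channels")
  nz <- npages %/% nc

  axes <- toupper(meta$axes %||% "ZCYX")
  if (!axes %in% c("ZCYX", "CZYX"))
    stop("unsupported page order ", axes, " (expected ZCYX or CZYX)")
  message("page order ", axes, " (", nz, " slices x ", nc, " channels)")
  page_of <- if (axes == "ZCYX") {
    function(z, c) (z - 1L) * nc + c
  } else {
    function(z, c) (c - 1L) * nz + z
  }

  ny <- nrow(tf$pages[[1]]); nx <- ncol(tf$pages[[1]])
  voxels <- lapply(seq_len(nc), function(ci) {
    a <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) a[z, , ] <- tf$pages[[page_of(z, ci)]]
    a
  })

  spacing <- meta$spacing
  if (!is.null(spacing_override)) {
    if (!is.null(spacing))
      message("spacing override (", paste(spacing_override, collapse = ", "),
              ") replaces stored spacing (",
              paste(signif(spacing, 6), collapse = ", "), ")")
    spacing <- spacing_override
  }
  if (is.null(spacing))
    stop("no voxel spacing in file metadata; pass `spacing_override`")
  image_stack(voxels, spacing = spacing, channels = channels,
              depth_origin = meta$depth_origin %||% 0)
}

#' Write an image stack as a multipage TIFF
#'
#' Pages are written in `ZCYX` order (slice-major, channel-minor) with
#' spacing, channel roles and depth origin embedded as JSON in the
#' ImageDescription tag, so [read_stack()] round-trips the stack bit-exactly.
#' Integer-valued stacks are stored at 8 or 16 bit; anything else as 64-bit
#' float.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels[[1]])
  nz <- d[1]; nc <- length(stack$channels)
  allv <- unlist(stack$voxels, use.names = FALSE)
  integerish <- all(allv == round(allv))
  mx <- if (length(allv)) max(allv) else 0
  if (integerish && mx <= 255) {
    bits <- 8L; sf <- 1L
  } else if (integerish && mx <= 65535) {
    bits <- 16L; sf <- 1L
  } else {
    bits <- 64L; sf <- 3L
  }
  pages <- vector("list", nz * nc)
  k <- 0L
  for (z in seq_len(nz)) {
    for (ci in seq_len(nc)) {
      k <- k + 1L
      pages[[k]] <- stack$voxels[[ci]][z, , ]
    }
  }
  desc <- jsonlite::toJSON(
    list(axes = "ZCYX", shape = c(nz, nc, d[2], d[3]),
         spacing = stack$spacing, channels = stack$channels,
         depth_origin = stack$depth_origin),
    auto_unbox = FALSE, digits = NA)
  write_tiff_pages(path, pages, bits = bits, sample_format = sf,
                   desc = as.character(desc))
  invisible(path)
}

# columns every metrics table carries, in order
metrics_id_cols <- c("sample_id", "group", "site")
metrics_value_cols <- c("volume_fraction", "surface_area_um2", "n_branches",
                        "n_fibres", "mean_length_um", "mean_diameter_um",
                        "mean_curvature_per_um", "intensity_ratio")

#' Create a metrics record
#'
#' One row of per-field morphometry results. Metrics that were not computed
#' stay `NA` (explicitly absent, never silently zero).
#'
#' @param sample_id,group,site Identifier strings (`group` is e.g.
#'   `"young"` / `"aged"`).
#' @param ... Named metric values among `volume_fraction`,
#'   `surface_area_um2`, `n_branches`, `n_fibres`, `mean_length_um`,
#'   `mean_diameter_um`, `mean_curvature_per_um`, `intensity_ratio`.
#' @return A one-row `data.frame`.
#' @export
metrics_record <- function(sample_id, group = NA_character_,
                           site = NA_character_, ...) {
  vals <- list(...)
  bad <- setdiff(names(vals), metrics_value_cols)
  if (length(bad)) stop("unknown metric field(s): ", paste(bad, collapse = ", "))
  rec <- as.list(setNames(rep(NA_real_, length(metrics_value_cols)),
                          metrics_value_cols))
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.na(v) && !is.finite(v)) stop("metric ", nm, " must be finite")
    rec[[nm]] <- as.numeric(v)
  }
  cbind(data.frame(sample_id = as.character(sample_id),
                   group = as.character(group), site = as.character(site),
                   stringsAsFactors = FALSE),
        as.data.frame(rec))
}

#' Write / read metrics tables
#'
#' RFC-4180 CSV with a header row; numeric values round-trip to full double
#' precision; `NA` marks metrics that were not computed.
#'
#' @param records A `data.frame` of [metrics_record()] rows.
#' @param path CSV file path.
#' @return `read_metrics` returns the `data.frame`; `write_metrics` returns
#'   `path` invisibly.
#' @export
write_metrics <- function(records, path) {
  stopifnot(is.data.frame(records))
  data.table::fwrite(records, path, na = "NA", quote = "auto")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, na.strings = "NA", data.table = FALSE)
  if (!all(metrics_id_cols %in% names(dt)))
    stop("malformed metrics CSV: missing ",
         paste(setdiff(metrics_id_cols, names(dt)), collapse = ", "))
  for (cl in intersect(metrics_value_cols, names(dt)))
    dt[[cl]] <- as.numeric(dt[[cl]])
  dt
}
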