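#' Multichannel 3D image stack
#'
#' Container for a multichannel volumetric fluorescence image. Voxel arrays
#' are indexed `(z, y, x)` (slice, row, column) and spacing is `(dz, dy, dx)`
#' in micrometres; physical coordinates reported by downstream functions are
#' `(x, y, z)` micrometres with the first voxel centre at
#' `(0, 0, depth_origin)`. Depth increases with the z index (slice 1 is the
#' most superficial, e.g. the epidermal surface).
#'
#' @param voxels A 3D numeric array `(z, y, x)` for a single channel, or a
#'   list of such arrays (one per channel, identical dimensions).
#' @param spacing Numeric length-3, voxel spacing `(dz, dy, dx)` in
#'   micrometres; all strictly positive.
#' @param channels Character vector of channel role labels (e.g.
#'   `c("nuclei", "tropoelastin", "fibrillin1")`), one per voxel array.
#' @param depth_origin z-position (micrometres) of the first slice relative
#'   to the reference surface. Default 0.
#' @return An object of class `image_stack`: a list with elements `voxels`
#'   (named list of 3D arrays), `spacing`, `channels`, `depth_origin`.
#' @examples
#' vol <- array(0, dim = c(8, 16, 16))
#' s <- image_stack(vol, spacing = c(0.8, 0.75, 0.75),
#'                  channels = "tropoelastin")
#' dim(s$voxels$tropoelastin)
#' @export
image_stack <- function(voxels, spacing, channels, depth_origin = 0) {
  if (is.array(voxels) && length(dim(voxels)) == 3L) voxels <- list(voxels)
  if (!is.list(voxels) || length(voxels) == 0L)
    stop("`voxels` must be a 3D array or a non-empty list of 3D arrays")
  if (length(channels) != length(voxels))
    stop("channel count mismatch: ", length(voxels), " voxel arrays but ",
         length(channels), " channel labels")
  dims <- lapply(voxels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array indexed (z, y, x)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share one grid shape")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (dz, dy, dx)")
  for (v in voxels) {
    if (any(!is.finite(v))) stop("intensities must be finite")
    if (min(v) < 0) stop("intensities must be >= 0")
  }
  names(voxels) <- channels
  structure(list(voxels = voxels, spacing = spacing,
                 channels = as.character(channels),
                 depth_origin = as.numeric(depth_origin)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels[[1]])
  cat(sprintf("<image_stack> %d slices x %d x %d, %d channel(s): %s\n",
              d[1], d[2], d[3], length(x$channels),
              paste(x$channels, collapse = ", ")))
  cat(sprintf("  spacing (dz, dy, dx) = (%g, %g, %g) um; depth origin %g um\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$depth_origin))
  invisible(x)
}

#' Binary foreground mask on an image grid
#'
#' @param voxels 3D logical array `(z, y, x)`.
#' @param spacing Voxel spacing `(dz, dy, dx)` in micrometres.
#' @param depth_origin z-position (micrometres) of the first slice.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, depth_origin = 0) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask may not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values")
  structure(list(voxels = voxels, spacing = spacing,
                 depth_origin = as.numeric(depth_origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d (z, y, x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

# physical volume of one voxel in um^3
voxel_volume_um3 <- function(x) prod(x$spacing)

# physical (x, y, z) um coordinates of 1-based voxel indices (z, y, x)
voxel_to_um <- function(idx_zyx, spacing, depth_origin = 0) {
  idx_zyx <- matrix(idx_zyx, ncol = 3)
  cbind(x = (idx_zyx[, 3] - 1) * spacing[3],
        y = (idx_zyx[, 2] - 1) * spacing[2],
        z = depth_origin + (idx_zyx[, 1] - 1) * spacing[1])
}

# fractional 0-based (z, y, x) voxel coordinates of physical (x, y, z) points
um_to_voxel <- function(pts_xyz, spacing, depth_origin = 0) {
  pts_xyz <- matrix(pts_xyz, ncol = 3)
  cbind((pts_xyz[, 3] - depth_origin) / spacing[1],
        pts_xyz[, 2] / spacing[2],
        pts_xyz[, 1] / spacing[3])
}

#' Crop a stack to a maximum imaging depth
#'
#' Confocal signal in cleared tissue degrades with depth, so analysis is
#' restricted to the superficial part of the acquisition (default 100 um).
#' Slices whose z-position `depth_origin + (k - 1) * dz` does not exceed
#' `max_depth_um` are retained; the comparison is inclusive, so with
#' `dz = 0.8` and a depth limit of 100 the slice at exactly 100.0 um is the
#' last one kept.
#'
#' @param stack An [image_stack()].
#' @param max_depth_um Maximum depth in micrometres (default 100).
#' @return The cropped `image_stack` (spacing and depth origin unchanged).
#' @examples
#' s <- image_stack(array(0, c(188, 4, 4)), c(0.8, 1, 1), "tropoelastin")
#' dim(crop_to_depth(s, 100)$voxels[[1]])[1] # 126 slices: z = 0 ... 100.0
#' @export
crop_to_depth <- function(stack, max_depth_um = 100) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(max_depth_um) || length(max_depth_um) != 1L ||
      max_depth_um <= 0)
    stop("`max_depth_um` must be a positive number")
  dz <- stack$spacing[1]
  nz <- dim(stack$voxels[[1]])[1]
  zpos <- stack$depth_origin + (seq_len(nz) - 1) * dz
  keep <- zpos <= max_depth_um + 1e-9
  if (!any(keep))
    stop("no slices at or above depth ", max_depth_um,
         " um (first slice is at ", stack$depth_origin, " um)")
  if (all(keep)) return(stack)
  stack$voxels <- lapply(stack$voxels,
                         function(v) v[keep, , , drop = FALSE])
  stack
}
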