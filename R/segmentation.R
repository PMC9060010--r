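# Binarization of a fibre channel. The imaging study this package models
# states only that stacks were "processed for binarization"; the defaults
# here (per-volume Otsu on a 256-bin histogram, 26-connected speckle
# removal at 10 um^3) are declared package choices, not reproductions.

#' Preprocess a fibre channel
#'
#' Gaussian smoothing in physical units (sigma is divided per axis by the
#' voxel spacing) with optional rolling-ball-style background subtraction
#' (grey opening with a box structuring element of the given physical
#' radius, subtracted from the image). Output is clipped at zero.
#'
#' @param channel 3D numeric array `(z, y, x)`.
#' @param spacing Voxel spacing `(dz, dy, dx)` micrometres.
#' @param smooth_sigma_um Gaussian sigma `(sz, sy, sx)` in micrometres;
#'   0 disables smoothing along that axis.
#' @param background_radius_um Optional physical radius of the background
#'   structuring element; `NULL` (default) disables background subtraction.
#' @return The filtered 3D array (same dimensions, all values >= 0).
#' @export
preprocess <- function(channel, spacing, smooth_sigma_um = c(0, 0, 0),
                       background_radius_um = NULL) {
  stopifnot(is.array(channel), length(dim(channel)) == 3L)
  smooth_sigma_um <- rep_len(as.numeric(smooth_sigma_um), 3L)
  if (any(smooth_sigma_um < 0)) stop("smoothing sigma must be >= 0")
  d <- dim(channel)
  out <- channel
  if (any(smooth_sigma_um > 0)) {
    sig_vox <- smooth_sigma_um / spacing
    out <- array(cpp_gaussian_blur(as.numeric(out), d, sig_vox), dim = d)
  }
  if (!is.null(background_radius_um)) {
    if (background_radius_um <= 0) stop("background radius must be > 0")
    rad <- pmax(1L, as.integer(round(background_radius_um / spacing)))
    bg <- cpp_box_extremum(as.numeric(out), d, rad, FALSE) # erosion
    bg <- cpp_box_extremum(bg, d, rad, TRUE)               # then dilation
    out <- array(pmax(as.numeric(out) - bg, 0), dim = d)
  }
  out[out < 0] <- 0
  out
}

#' Otsu threshold of an intensity sample
#'
#' Exhaustive maximization of the between-class variance over a 256-bin
#' histogram. Returned threshold is the upper edge of the best background
#' bin, on the intensity scale of the input.
#'
#' @param x Numeric vector (or array) of intensities with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return Scalar threshold; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    stop("cannot apply Otsu thresholding to a constant image")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                     n_bins), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance for a split after bin k
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  breaks[k + 1L]
}

#' Binarize a fibre channel
#'
#' @param channel 3D numeric array `(z, y, x)`.
#' @param spacing Voxel spacing `(dz, dy, dx)` micrometres.
#' @param method `"otsu"` (per-volume, 256-bin; the default) or a fixed
#'   numeric threshold.
#' @param depth_origin Passed through to the mask.
#' @return A [binary_mask()]; the threshold used is attached as attribute
#'   `"threshold"`.
#' @examples
#' ch <- array(10, c(8, 8, 8)); ch[4:5, 4:5, 4:5] <- 100
#' m <- binarize(ch, c(1, 1, 1))
#' attr(m, "threshold") # strictly between 10 and 100
#' @export
binarize <- function(channel, spacing, method = "otsu", depth_origin = 0) {
  stopifnot(is.array(channel), length(dim(channel)) == 3L)
  if (identical(method, "otsu")) {
    thr <- otsu_threshold(channel)
  } else if (is.numeric(method) && length(method) == 1L) {
    thr <- method
    rng <- range(channel)
    if (thr < rng[1] || thr >= rng[2])
      warning("fixed threshold ", thr, " is outside the intensity range [",
              signif(rng[1], 6), ", ", signif(rng[2], 6),
              "]: mask is empty or full")
  } else {
    stop("`method` must be \"otsu\" or a single numeric threshold")
  }
  mask <- binary_mask(channel > thr, spacing, depth_origin)
  attr(mask, "threshold") <- thr
  mask
}

#' Remove small connected components
#'
#' Deletes foreground components whose physical volume is below
#' `min_volume_um3` (speckle suppression ahead of skeletonization).
#' Idempotent and anti-extensive.
#'
#' @param mask A [binary_mask()].
#' @param min_volume_um3 Minimum component volume to keep (default 10).
#' @param connectivity 6, 18 or 26 (default 26: diagonal fibre continuity).
#' @return The filtered [binary_mask()].
#' @export
remove_small_components <- function(mask, min_volume_um3 = 10,
                                    connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"), min_volume_um3 >= 0)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (min_volume_um3 == 0 || !any(mask$voxels)) return(mask)
  d <- dim(mask$voxels)
  lab <- cpp_label_components(as.logical(mask$voxels), d,
                              as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which(sizes * voxel_volume_um3(mask) >= min_volume_um3)
  out <- array(lab %in% keep & lab > 0L, dim = d)
  binary_mask(out, mask$spacing, mask$depth_origin)
}
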