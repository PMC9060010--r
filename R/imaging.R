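# Forward imaging model: turns a crisp phantom mask into something that
# looks like a confocal acquisition of cleared tissue (PSF blur, constant
# background, Gaussian/Poisson noise, exponential loss of signal with depth).

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Confocal imaging model for phantom rendering
#'
#' @param psf_sigma Gaussian PSF standard deviations
#'   `(sigma_z, sigma_y, sigma_x)` in micrometres (axial blur is typically
#'   about twice the lateral blur; defaults `(1.0, 0.5, 0.5)` are generic
#'   confocal values, not fitted to any instrument).
#' @param gaussian_sd Additive Gaussian noise SD (intensity units).
#' @param poisson_scale Photon-counting scale: voxel values are replaced by
#'   `rpois(value * scale) / scale` when `> 0`; 0 disables shot noise.
#' @param attenuation_um Depth attenuation length zeta (micrometres): signal
#'   is multiplied by `exp(-z / zeta)`. `Inf` (default) disables
#'   attenuation; cleared-skin acquisitions lose signal noticeably beyond
#'   about 100 um depth.
#' @param background Constant background offset (intensity units).
#' @param seed Integer RNG seed; identical seed + parameters give identical
#'   output. Mandatory.
#' @return An `imaging_model` object.
#' @export
imaging_model <- function(psf_sigma = c(1.0, 0.5, 0.5), gaussian_sd = 0,
                          poisson_scale = 0, attenuation_um = Inf,
                          background = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  psf_sigma <- rep_len(as.numeric(psf_sigma), 3L)
  if (any(psf_sigma < 0) || gaussian_sd < 0 || poisson_scale < 0 ||
      background < 0 || attenuation_um <= 0)
    stop("imaging model parameters must be non-negative (attenuation > 0)")
  structure(list(psf_sigma = psf_sigma, gaussian_sd = gaussian_sd,
                 poisson_scale = poisson_scale,
                 attenuation_um = attenuation_um,
                 background = background, seed = as.integer(seed)),
            class = "imaging_model")
}

render_channel <- function(field, spacing, model, depth_origin, seed) {
  d <- dim(field)
  sig_vox <- model$psf_sigma / spacing
  v <- field
  if (any(sig_vox > 0))
    v <- array(cpp_gaussian_blur(as.numeric(v), d, sig_vox), dim = d)
  if (is.finite(model$attenuation_um)) {
    zpos <- depth_origin + (seq_len(d[1]) - 1) * spacing[1]
    v <- v * exp(-zpos / model$attenuation_um)
  }
  v <- v + model$background
  with_local_seed(seed, {
    if (model$poisson_scale > 0)
      v <- array(rpois(length(v), pmax(v, 0) * model$poisson_scale) /
                   model$poisson_scale, dim = d)
    if (model$gaussian_sd > 0)
      v <- v + array(rnorm(length(v), 0, model$gaussian_sd), dim = d)
  })
  v[v < 0] <- 0
  v
}

#' Render a phantom through the imaging model
#'
#' `intensity = blur(peak * mask) * exp(-z / zeta) + background + noise`,
#' clipped at zero. Deterministic for a fixed model seed.
#'
#' @param mask A [binary_mask()] (or a numeric 3D array already carrying
#'   intensities, in which case `peak_intensity` scales it).
#' @param model An [imaging_model()].
#' @param peak_intensity Foreground intensity before blur (default 100).
#' @param channel Channel role label for the output stack.
#' @return A single-channel [image_stack()].
#' @export
render_acquisition <- function(mask, model, peak_intensity = 100,
                               channel = "tropoelastin") {
  stopifnot(inherits(model, "imaging_model"))
  if (inherits(mask, "binary_mask")) {
    field <- array(as.numeric(mask$voxels) * peak_intensity,
                   dim = dim(mask$voxels))
    spacing <- mask$spacing
    depth_origin <- mask$depth_origin
  } else {
    stop("`mask` must be a binary_mask")
  }
  v <- render_channel(field, spacing, model, depth_origin, model$seed)
  image_stack(v, spacing = spacing, channels = channel,
              depth_origin = depth_origin)
}

#' Render a two-channel phantom with a known intensity ratio
#'
#' Both channels share the phantom geometry; the second
#' (fibrillin-1) channel is rendered with peak intensity
#' `ratio * peak_intensity` and an independent seed-derived noise stream, so
#' the downstream [channel_intensity_ratio()] has `ratio` as its noise-free
#' ground truth.
#'
#' @inheritParams render_acquisition
#' @param ratio Target fibrillin-1 / tropoelastin intensity ratio (> 0).
#' @return A two-channel [image_stack()] (`tropoelastin`, `fibrillin1`).
#' @export
make_two_channel <- function(mask, model, ratio, peak_intensity = 100) {
  stopifnot(inherits(mask, "binary_mask"), inherits(model, "imaging_model"))
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("`ratio` must be a positive number")
  field <- array(as.numeric(mask$voxels), dim = dim(mask$voxels))
  ch1 <- render_channel(field * peak_intensity, mask$spacing, model,
                        mask$depth_origin, model$seed)
  ch2 <- render_channel(field * peak_intensity * ratio, mask$spacing, model,
                        mask$depth_origin, model$seed + 1000003L)
  image_stack(list(ch1, ch2), spacing = mask$spacing,
              channels = c("tropoelastin", "fibrillin1"),
              depth_origin = mask$depth_origin)
}

#' Phantom population template
#'
#' Distribution parameters for a cohort of phantoms, used to emulate e.g.
#' young-like vs aged-like groups. Curvature (of arc-based geometry) and
#' tube radius are drawn lognormally with the given mean and coefficient of
#' variation (a CV of 0 gives the template value exactly).
#'
#' @param kind `"arc"` (single arched fibre), `"candelabra"`
#'   (arched base + prongs, see [make_candelabra()]), or `"field"`
#'   (candelabra plus arched elaunin-like fibres, see
#'   [make_field_phantom()]; the kind to use for cohort studies, since one
#'   field then carries branch, curvature and diameter signals).
#' @param curvature_mean Mean centreline curvature (1/um) of the arc or of
#'   the candelabra base.
#' @param curvature_cv Coefficient of variation of curvature.
#' @param tube_radius_mean,tube_radius_cv Lognormal tube radius (um).
#' @param n_prongs Candelabra prong count (ground-truth branch count).
#' @param prong_length,jitter_sd,base_depth Candelabra geometry,
#'   micrometres.
#' @param arc_length Arc length (um) of the `"arc"` geometry (fixed; the
#'   angular span adapts to the drawn radius).
#' @param spacing Voxel spacing for rasterization.
#' @return A `population_template` object.
#' @export
population_template <- function(kind = c("arc", "candelabra", "field"),
                                curvature_mean = 1 / 30, curvature_cv = 0.15,
                                tube_radius_mean = 2, tube_radius_cv = 0.1,
                                n_prongs = 4L, prong_length = 25,
                                jitter_sd = 0.5, base_depth = 35,
                                arc_length = 40, spacing = c(1, 1, 1)) {
  kind <- match.arg(kind)
  stopifnot(curvature_mean > 0, curvature_cv >= 0, tube_radius_mean > 0,
            tube_radius_cv >= 0, arc_length > 0)
  structure(list(kind = kind, curvature_mean = curvature_mean,
                 curvature_cv = curvature_cv,
                 tube_radius_mean = tube_radius_mean,
                 tube_radius_cv = tube_radius_cv,
                 n_prongs = as.integer(n_prongs),
                 prong_length = prong_length, jitter_sd = jitter_sd,
                 base_depth = base_depth, arc_length = arc_length,
                 spacing = spacing), class = "population_template")
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a phantom population
#'
#' Draws `n` phantoms from a [population_template()]; reproducible for a
#' fixed seed (phantom i uses derived seed `seed * 1000 + i`).
#'
#' @param template A [population_template()].
#' @param n Number of phantoms (>= 1).
#' @param seed Integer seed.
#' @return List of `n` elements, each `(mask, truth)`; each `truth` also
#'   records the drawn parameters.
#' @export
make_population <- function(template, n, seed) {
  stopifnot(inherits(template, "population_template"), n >= 1)
  draws <- with_local_seed(seed, list(
    kappa = rlnorm_mean_cv(n, template$curvature_mean, template$curvature_cv),
    r = rlnorm_mean_cv(n, template$tube_radius_mean, template$tube_radius_cv)))
  lapply(seq_len(n), function(i) {
    kappa <- draws$kappa[i]
    r <- draws$r[i]
    ph <- if (template$kind == "arc") {
      R <- 1 / kappa
      span <- template$arc_length / R
      rasterize_tube(tube_arc(centre = c(0, 0, 0), radius = R, r = r,
                              span = span, plane = "xy"),
                     spacing = template$spacing)
    } else if (template$kind == "candelabra") {
      # candelabra base sag follows the drawn curvature:
      # for a shallow arc of half-width h, R = (h^2 + s^2) / (2 s)
      h <- template$arc_length / 2
      s <- 1 / kappa - sqrt(max(1 / kappa^2 - h^2, 0))
      make_candelabra(n_prongs = template$n_prongs,
                      base_depth = template$base_depth,
                      prong_length = template$prong_length,
                      tube_radius = r, jitter_sd = template$jitter_sd,
                      seed = seed * 1000L + i,
                      base_span = template$arc_length, base_sag = s,
                      spacing = template$spacing)
    } else {
      make_field_phantom(n_prongs = template$n_prongs,
                         arc_curvature = kappa,
                         base_depth = template$base_depth,
                         prong_length = template$prong_length,
                         tube_radius = r, jitter_sd = template$jitter_sd,
                         seed = seed * 1000L + i,
                         base_span = template$arc_length,
                         spacing = template$spacing)
    }
    ph$truth$drawn_curvature_per_um <- kappa
    ph$truth$drawn_tube_radius_um <- r
    ph
  })
}
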