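## Rasterization of phantoms into echo-like voxel volumes.
##
## Intensity model (fixed so downstream threshold configs stay stable):
## tissue 200, blood/background 30, optional additive Gaussian noise,
## intensities clipped to [0, 255].

TISSUE_INTENSITY <- 200
BACKGROUND_INTENSITY <- 30

## Fill voxels whose centers are nearest to a dense set of world points.
splat_points <- function(arr, vol_geom, pts, value) {
  d <- dim(arr)
  idx <- round(world_to_index(vol_geom, pts))
  keep <- idx[, 1L] >= 1 & idx[, 1L] <= d[1L] &
          idx[, 2L] >= 1 & idx[, 2L] <= d[2L] &
          idx[, 3L] >= 1 & idx[, 3L] <= d[3L]
  if (!all(keep))
    stop_trimorph("phantom surface exceeds the volume bounds", "trimorph_bounds_error")
  arr[idx] <- value
  arr
}

#' Voxelize a valve phantom into an echo-like volume
#'
#' Renders the leaflet surface (annulus included) as high-intensity voxels
#' over a low-intensity background, adds optional Gaussian noise, and emits
#' the ground-truth landmark annotation alongside, with every landmark
#' snapped to a voxel center (an idealized manual annotation on that grid).
#'
#' @param spec a [leaflet_spec()].
#' @param spacing isotropic voxel size, mm.
#' @param margin padding around the phantom bounding box, mm.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param seed RNG seed for the noise (volume is byte-identical per seed).
#' @param vol_geom optional [voxel_volume()] giving an explicit grid; a
#'   surface outside its extents is a bounds error.
#' @param n_trace trace points per station passed to [phantom_landmarks()].
#' @return list with `volume` (a [voxel_volume()]) and `annotation`
#'   (an [annulus_landmarks()] set).
#' @export
voxelize_valve <- function(spec, spacing = 0.5, margin = 6, noise_sd = 0,
                           seed = 1L, vol_geom = NULL, n_trace = 10L) {
  stopifnot(inherits(spec, "leaflet_spec"))
  assert_scalar_num(spacing, "spacing", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  ## dense surface sampling: steps below spacing/2 in world units
  th_probe <- seq(0, 2 * pi, length.out = 721L)
  r_max <- max(sqrt(rowSums(
    sweep(annulus_eval(spec$annulus, th_probe), 2L, spec$annulus$a[, 1L])^2)))
  n_t <- max(64L, ceiling(2 * pi * r_max / (spacing / 2.5)))
  n_f <- max(16L, ceiling(r_max / (spacing / 2.5)))
  th <- seq(0, 2 * pi, length.out = n_t + 1L)[-(n_t + 1L)]
  f <- seq(0, 1, length.out = n_f)
  grid <- expand.grid(f = f, th = th)
  surf <- leaflet_surface(spec, grid$f, grid$th)
  if (is.null(vol_geom)) {
    lo <- apply(surf, 2L, min) - margin
    hi <- apply(surf, 2L, max) + margin
    dims <- pmax(2L, ceiling((hi - lo) / spacing) + 1L)
    vol_geom <- voxel_volume(array(BACKGROUND_INTENSITY, dims),
                             spacing = spacing, origin = lo)
  }
  arr <- array(BACKGROUND_INTENSITY, dim(vol_geom$data))
  arr <- splat_points(arr, vol_geom, surf, TISSUE_INTENSITY)
  if (noise_sd > 0) {
    arr <- arr + with_seed(seed, array(rnorm(length(arr), 0, noise_sd), dim(arr)))
    arr[arr < 0] <- 0; arr[arr > 255] <- 255
  }
  vol <- voxel_volume(arr, spacing = vol_geom$spacing, origin = vol_geom$origin)
  ann <- phantom_landmarks(spec, n_trace = n_trace, snap_to = vol)
  list(volume = vol, annotation = ann)
}

#' Right-ventricle phantom specification
#'
#' @param semi_axes ellipsoid semi-axes (a, b, c), mm, all positive.
#' @param center cavity center, mm.
#' @param cavity_intensity,wall_intensity voxel intensities of the blood pool
#'   and surrounding tissue (defaults: dark cavity in bright tissue).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @return An object of class `rv_phantom_spec`.
#' @export
rv_phantom_spec <- function(semi_axes = c(50, 40, 22.2), center = c(0, 0, 0),
                            cavity_intensity = BACKGROUND_INTENSITY,
                            wall_intensity = TISSUE_INTENSITY,
                            noise_sd = 0, seed = 1L) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop_trimorph("semi_axes must be three positive numbers", "trimorph_invalid_parameter")
  if (cavity_intensity == wall_intensity)
    stop_trimorph("cavity and wall intensities must differ", "trimorph_invalid_parameter")
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(semi_axes = semi_axes, center = as.numeric(center),
                 cavity_intensity = cavity_intensity,
                 wall_intensity = wall_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "rv_phantom_spec")
}

#' Build an ellipsoidal RV cavity phantom
#'
#' Voxels whose centers fall inside the ellipsoid carry the cavity intensity;
#' everything else is wall. The analytic cavity volume (4/3) pi a b c is
#' returned as ground truth.
#'
#' @param spec an [rv_phantom_spec()].
#' @param spacing isotropic voxel size, mm.
#' @param margin wall thickness around the cavity bounding box, mm.
#' @param vol_geom optional explicit grid; the ellipsoid must fit inside.
#' @return list with `volume` (a [voxel_volume()]) and `true_volume` (mL).
#' @export
build_rv_phantom <- function(spec, spacing = 0.5, margin = 8, vol_geom = NULL) {
  stopifnot(inherits(spec, "rv_phantom_spec"))
  assert_scalar_num(spacing, "spacing", positive = TRUE)
  ax <- spec$semi_axes
  if (is.null(vol_geom)) {
    lo <- spec$center - ax - margin
    dims <- ceiling((2 * (ax + margin)) / spacing) + 1L
    vol_geom <- voxel_volume(array(0, dims), spacing = spacing, origin = lo)
  } else {
    lo_need <- spec$center - ax; hi_need <- spec$center + ax
    d <- dim(vol_geom$data)
    hi_have <- vol_geom$origin + (d - 1L) * vol_geom$spacing
    if (any(lo_need < vol_geom$origin) || any(hi_need > hi_have))
      stop_trimorph("ellipsoid exceeds the volume bounds", "trimorph_bounds_error")
  }
  co <- vox_axis_coords(vol_geom)
  xs <- (co[[1L]] - spec$center[1L]) / ax[1L]
  ys <- (co[[2L]] - spec$center[2L]) / ax[2L]
  zs <- (co[[3L]] - spec$center[3L]) / ax[3L]
  d <- dim(vol_geom$data)
  rsq <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  arr <- array(spec$wall_intensity, d)
  arr[rsq <= 1] <- spec$cavity_intensity
  if (spec$noise_sd > 0) {
    arr <- arr + with_seed(spec$seed,
                           array(rnorm(length(arr), 0, spec$noise_sd), d))
    arr[arr < 0] <- 0; arr[arr > 255] <- 255
  }
  list(volume = voxel_volume(arr, spacing = vol_geom$spacing,
                             origin = vol_geom$origin),
       true_volume = 4 / 3 * pi * prod(ax) / 1000)
}
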