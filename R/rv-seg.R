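## Semi-automatic right-ventricle volumetry.
##
## Four steps mirroring an interactive active-contour workflow, made fully
## scriptable: (i) manual ROI crop, (ii) threshold-based speed image in
## [-1, 1], (iii) seeded region growing restricted to positive speed,
## (iv) scripted refinement edits, then voxel-count volume quantification.
## The continuous contour evolution is simplified to monotone 6-connected
## front growth on s > 0; on binary speed images (hard thresholds, high
## contrast) this equals thresholded connected-component labeling.

#' Crop a volume to a region of interest
#'
#' @param vol a [voxel_volume()].
#' @param box_min,box_max opposite ROI corners, world mm.
#' @return A [voxel_volume()] sub-volume; world coordinates of retained
#'   voxels are unchanged (the origin is adjusted).
#' @export
crop_roi <- function(vol, box_min, box_max) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  lo <- pmax(1L, ceiling(world_to_index(vol, matrix(pmin(box_min, box_max), 1L)) - 1e-9))
  hi <- pmin(d, floor(world_to_index(vol, matrix(pmax(box_min, box_max), 1L)) + 1e-9))
  if (any(lo > hi))
    stop_trimorph("ROI does not intersect the volume", "trimorph_bounds_error")
  lo <- as.integer(lo); hi <- as.integer(hi)
  sub <- vol$data[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  voxel_volume(sub, spacing = vol$spacing,
               origin = vol$origin + (lo - 1L) * vol$spacing)
}

#' Threshold specification for the speed image
#'
#' @param lower,upper intensity window; intensities inside map to speed +1.
#' @param ramp_width width of the linear -1 to +1 transition at each window
#'   edge; 0 gives a hard binary map.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(lower, upper, ramp_width = 0) {
  assert_scalar_num(lower, "lower"); assert_scalar_num(upper, "upper")
  assert_scalar_num(ramp_width, "ramp_width", nonneg = TRUE)
  if (lower > upper)
    stop_trimorph("lower threshold exceeds upper", "trimorph_invalid_parameter")
  structure(list(lower = lower, upper = upper, ramp_width = ramp_width),
            class = "threshold_spec")
}

#' Transform an anatomical image into a speed image
#'
#' Intensities inside `[lower, upper]` map to +1 and intensities more than
#' `ramp_width` beyond the window to -1, with a linear -1 to +1 ramp over
#' the `ramp_width` band just outside each window edge (so `lower -
#' ramp_width/2` maps to 0).
#'
#' @param vol a [voxel_volume()].
#' @param thr a [threshold_spec()].
#' @return An object of class `speed_image`: list with `data` in [-1, 1],
#'   `spacing`, `origin`.
#' @export
compute_speed_image <- function(vol, thr) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(thr, "threshold_spec"))
  x <- vol$data
  w <- thr$ramp_width
  if (w == 0) {
    s <- ifelse(x >= thr$lower & x <= thr$upper, 1, -1)
  } else {
    s_lo <- pmin(1, pmax(-1, (x - thr$lower + w) * (2 / w) - 1))
    s_hi <- pmin(1, pmax(-1, (thr$upper + w - x) * (2 / w) - 1))
    s <- pmin(s_lo, s_hi)
  }
  structure(list(data = array(s, dim(x)), spacing = vol$spacing,
                 origin = vol$origin),
            class = "speed_image")
}

#' Seeded region growing on a speed image
#'
#' Iterative 6-connected front propagation from the seeds into voxels with
#' positive speed; terminates when no candidate remains (the endocardial
#' border, where speed turns negative) or when `max_iter` front layers have
#' been grown (flagged).
#'
#' @param speed a `speed_image`.
#' @param seeds matrix (or vector) of 1-based voxel indices, one seed per
#'   row; every seed must sit on positive speed.
#' @param max_iter maximum number of front layers; `Inf` for unbounded.
#' @return An object of class `segmentation_mask`: list with logical `data`,
#'   `spacing`, `origin`, `capped`.
#' @export
region_grow <- function(speed, seeds, max_iter = Inf) {
  stopifnot(inherits(speed, "speed_image"))
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  cap <- if (is.infinite(max_iter)) -1L else as.integer(max_iter)
  res <- tryCatch(
    .region_grow_cpp(as.numeric(speed$data), as.integer(dim(speed$data)),
                     seeds, cap),
    error = function(e) stop_trimorph(conditionMessage(e), "trimorph_bad_seed"))
  structure(list(data = array(res, dim(speed$data)), spacing = speed$spacing,
                 origin = speed$origin,
                 capped = isTRUE(attr(res, "capped"))),
            class = "segmentation_mask")
}

#' Scripted manual-refinement edits
#'
#' Edits are applied in order as voxel-set union (`add`) or difference
#' (`remove`) with a sphere or box in world coordinates; the scripted
#' stand-in for interactive clean-up of bubbles or the septal connector.
#'
#' @param mask a `segmentation_mask`.
#' @param edits list of edits, each a list with `op` ("add"/"remove"),
#'   `shape` ("sphere"/"box"), and `center`+`radius` (mm) or `min`+`max`.
#' @return The edited `segmentation_mask`.
#' @export
refine_mask <- function(mask, edits) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (length(edits) == 0L) return(mask)
  vol_geom <- voxel_volume(array(0, pmax(dim(mask$data), 2L)),
                           spacing = mask$spacing, origin = mask$origin)
  co <- vox_axis_coords(vol_geom)
  d <- dim(mask$data)
  hi <- mask$origin + (d - 1L) * mask$spacing
  for (e in edits) {
    if (!e$op %in% c("add", "remove") || !e$shape %in% c("sphere", "box"))
      stop_trimorph("edit must have op add/remove and shape sphere/box",
                    "trimorph_invalid_parameter")
    if (e$shape == "sphere") {
      ctr <- as.numeric(e$center); r <- e$radius
      if (any(ctr + r < mask$origin) || any(ctr - r > hi))
        stop_trimorph("edit shape lies outside the volume", "trimorph_bounds_error")
      sel <- outer(outer((co[[1L]] - ctr[1L])^2, (co[[2L]] - ctr[2L])^2, "+"),
                   (co[[3L]] - ctr[3L])^2, "+") <= r^2
    } else {
      lo <- pmin(as.numeric(e$min), as.numeric(e$max))
      up <- pmax(as.numeric(e$min), as.numeric(e$max))
      if (any(up < mask$origin) || any(lo > hi))
        stop_trimorph("edit shape lies outside the volume", "trimorph_bounds_error")
      inx <- co[[1L]] >= lo[1L] & co[[1L]] <= up[1L]
      iny <- co[[2L]] >= lo[2L] & co[[2L]] <= up[2L]
      inz <- co[[3L]] >= lo[3L] & co[[3L]] <= up[3L]
      sel <- outer(outer(inx, iny, "&"), inz, "&")
    }
    mask$data <- if (e$op == "add") mask$data | sel else mask$data & !sel
  }
  mask
}

#' Quantify the segmented volume
#'
#' @param mask a `segmentation_mask`.
#' @return volume, mL (`voxel count * prod(spacing) / 1000`).
#' @export
quantify_volume <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Full semi-automatic RV volumetry pipeline
#'
#' ROI crop, speed image, seeded region growing, scripted refinement,
#' volume quantification.
#'
#' @param vol a [voxel_volume()].
#' @param thr a [threshold_spec()].
#' @param seeds world-coordinate seed points, one per row (mm).
#' @param roi optional list with `min`/`max` corners, mm.
#' @param edits optional [refine_mask()] edit list.
#' @return list with `volume_ml`, `mask`, `capped`.
#' @export
segment_rv <- function(vol, thr, seeds, roi = NULL, edits = list()) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.null(roi)) vol <- crop_roi(vol, roi$min, roi$max)
  speed <- compute_speed_image(vol, thr)
  seed_idx <- round(world_to_index(vol, matrix(as.numeric(seeds), ncol = 3L)))
  mask <- region_grow(speed, seed_idx)
  mask <- refine_mask(mask, edits)
  list(volume_ml = quantify_volume(mask), mask = mask, capped = mask$capped)
}

#' Default threshold window for an RV phantom
#'
#' Cavity intensity plus/minus three noise SDs (floor of 5 intensity units),
#' hard map (ramp 0).
#'
#' @param spec an [rv_phantom_spec()].
#' @return A [threshold_spec()].
#' @export
default_rv_thresholds <- function(spec) {
  s <- max(spec$noise_sd, 5)
  threshold_spec(spec$cavity_intensity - 3 * s, spec$cavity_intensity + 3 * s)
}
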