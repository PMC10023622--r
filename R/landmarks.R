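## Annular / free-margin / papillary landmarks and their JSON annotation
## format. 18 angular stations at 20 degree spacing; stations k and k + 9
## live on one diametric image plane, which is how the annotation file
## groups them (9 planes, two points of each kind per plane).

N_STATIONS <- 18L
STATION_STEP_DEG <- 20

#' Construct an annular landmark set
#'
#' @param annular 18 x 3 matrix of annular points (mm), one per station at
#'   `k * 20` degrees, k = 0..17.
#' @param free_margin 18 x 3 matrix of leaflet free-margin points (mm).
#' @param apm optional anterior-papillary-muscle point (3-vector, mm).
#' @param traces optional list of 18 leaflet-trace polylines (n_i x 3
#'   matrices, mm), one per station, running from the annulus toward the
#'   coaptation center.
#' @param apex optional coaptation-center point (3-vector, mm).
#' @param axis optional long-axis record, list with `origin` and `direction`
#'   (ventricular); consumed by [define_long_axis()] in annotation mode.
#' @param angles_deg station azimuths; must be `0, 20, ..., 340`.
#' @return An object of class `annulus_landmarks`.
#' @export
annulus_landmarks <- function(annular, free_margin, apm = NULL, traces = NULL,
                              apex = NULL, axis = NULL,
                              angles_deg = seq(0, 340, by = STATION_STEP_DEG)) {
  annular <- as.matrix(annular); free_margin <- as.matrix(free_margin)
  if (length(angles_deg) != N_STATIONS ||
      max(abs(diff(angles_deg) - STATION_STEP_DEG)) > 1e-9)
    stop_trimorph("landmarks must have exactly 18 stations at 20 degree spacing",
                  "trimorph_invalid_parameter")
  if (!all(dim(annular) == c(N_STATIONS, 3L)) ||
      !all(dim(free_margin) == c(N_STATIONS, 3L)))
    stop_trimorph("annular and free_margin must be 18 x 3 matrices",
                  "trimorph_invalid_parameter")
  if (!is.null(traces) && length(traces) != N_STATIONS)
    stop_trimorph("traces must be a list of 18 polylines", "trimorph_invalid_parameter")
  structure(list(angles_deg = as.numeric(angles_deg), annular = annular,
                 free_margin = free_margin, apm = apm, traces = traces,
                 apex = apex, axis = axis),
            class = "annulus_landmarks")
}

#' @export
print.annulus_landmarks <- function(x, ...) {
  cat(sprintf("<annulus_landmarks> 18 stations, %s traces, APM %s\n",
              if (is.null(x$traces)) "no" else "with",
              if (is.null(x$apm)) "absent" else "present"))
  invisible(x)
}

#' Sample ground-truth landmarks from a valve phantom
#'
#' Places the 18 stations at exact azimuths `k * 20` degrees in the phantom's
#' axis frame, then reads annular, free-margin, trace and apex points off the
#' parametric surface. Optionally snaps every point to the nearest voxel
#' center of a target grid, emulating an annotator clicking on image voxels.
#'
#' @param spec a [leaflet_spec()].
#' @param n_trace number of leaflet-trace points per station (annulus
#'   excluded, running inward).
#' @param snap_to optional [voxel_volume()] whose grid landmark coordinates
#'   are snapped to.
#' @return An [annulus_landmarks()] set.
#' @export
phantom_landmarks <- function(spec, n_trace = 10L, snap_to = NULL) {
  stopifnot(inherits(spec, "leaflet_spec"))
  ann <- spec$annulus
  az <- seq(0, 340, by = STATION_STEP_DEG) * pi / 180
  th <- annulus_theta_at_azimuth(ann, az)
  annular <- annulus_eval(ann, th)
  f_fm <- 1 - spec$free_margin_fraction
  free_margin <- leaflet_surface(spec, rep(max(f_fm, 1e-3), N_STATIONS), th)
  f_tr <- seq(1, 0.08, length.out = n_trace + 1L)[-1L]
  traces <- lapply(seq_len(N_STATIONS), function(k)
    leaflet_surface(spec, f_tr, rep(th[k], n_trace)))
  apex <- as.numeric(leaflet_surface(spec, 0, th[1L]))
  ## APM reference point: ventricular of the apex, offset toward station 0
  apm <- apex + 12 * ann$axis_direction +
    0.25 * (annular[1L, ] - as.numeric(ann$a[, 1L]))
  snap <- function(m) {
    if (is.null(snap_to)) return(m)
    idx <- round(world_to_index(snap_to, m))
    index_to_world(snap_to, idx)
  }
  annulus_landmarks(snap(annular), snap(free_margin),
                    apm = as.numeric(snap(matrix(apm, 1L))),
                    traces = lapply(traces, snap),
                    apex = as.numeric(snap(matrix(apex, 1L))),
                    axis = list(origin = as.numeric(ann$axis_origin),
                                direction = as.numeric(ann$axis_direction)))
}

landmarks_to_json_list <- function(lm) {
  planes <- lapply(0:8, function(j) {
    k1 <- j + 1L; k2 <- j + 10L
    pl <- list(
      plane_angle_deg = lm$angles_deg[k1],
      annular_points = list(unname(lm$annular[k1, ]), unname(lm$annular[k2, ])),
      free_margin_points = list(unname(lm$free_margin[k1, ]),
                                unname(lm$free_margin[k2, ])))
    if (!is.null(lm$traces))
      pl$traces <- list(apply(lm$traces[[k1]], 1L, identity, simplify = FALSE),
                        apply(lm$traces[[k2]], 1L, identity, simplify = FALSE))
    if (j == 0L && !is.null(lm$apm)) pl$apm_point <- unname(lm$apm)
    pl
  })
  out <- list(planes = planes)
  if (!is.null(lm$apex)) out$apex_point <- unname(lm$apex)
  if (!is.null(lm$axis))
    out$long_axis <- list(origin = unname(lm$axis$origin),
                          direction = unname(lm$axis$direction))
  out
}

#' Write landmarks as a JSON annotation file
#'
#' One record per diametric image plane (`plane_angle_deg` 0..160), each with
#' the two annular and two free-margin points visible on that plane, optional
#' leaflet traces, and the single APM point on the first plane.
#'
#' @param lm an [annulus_landmarks()] set.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(lm, path) {
  stopifnot(inherits(lm, "annulus_landmarks"))
  jsonlite::write_json(landmarks_to_json_list(lm), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a JSON annotation file
#'
#' @param path annotation file written by [write_annotation()] (or by hand in
#'   the same schema).
#' @return An [annulus_landmarks()] set.
#' @export
read_annotation <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  planes <- doc$planes
  angles <- vapply(planes, function(p) as.numeric(p$plane_angle_deg), 0)
  expected <- seq(0, 160, by = STATION_STEP_DEG)
  missing <- setdiff(expected, round(angles))
  if (length(missing) > 0L)
    stop_trimorph(sprintf("annotation is missing plane angle(s): %s",
                          paste(missing, collapse = ", ")),
                  "trimorph_incomplete_annotation", missing_angles = missing)
  ord <- order(angles)
  planes <- planes[ord]
  getv <- function(x) as.numeric(unlist(x))
  annular <- matrix(NA_real_, N_STATIONS, 3L)
  free_margin <- matrix(NA_real_, N_STATIONS, 3L)
  traces <- vector("list", N_STATIONS)
  apm <- NULL
  for (j in seq_along(planes)) {
    p <- planes[[j]]
    annular[j, ] <- getv(p$annular_points[[1L]])
    annular[j + 9L, ] <- getv(p$annular_points[[2L]])
    free_margin[j, ] <- getv(p$free_margin_points[[1L]])
    free_margin[j + 9L, ] <- getv(p$free_margin_points[[2L]])
    if (!is.null(p$traces)) {
      traces[[j]] <- do.call(rbind, lapply(p$traces[[1L]], getv))
      traces[[j + 9L]] <- do.call(rbind, lapply(p$traces[[2L]], getv))
    }
    if (!is.null(p$apm_point)) apm <- getv(p$apm_point)
  }
  if (all(vapply(traces, is.null, TRUE))) traces <- NULL
  apex <- if (!is.null(doc$apex_point)) getv(doc$apex_point)
  axis <- if (!is.null(doc$long_axis))
    list(origin = getv(doc$long_axis$origin),
         direction = getv(doc$long_axis$direction))
  annulus_landmarks(annular, free_margin, apm = apm, traces = traces,
                    apex = apex, axis = axis)
}
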