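## Tricuspid annulus morphometry.
##
## Pipeline: long-axis definition -> 18 rotated half-planes -> landmark
## ingestion -> per-coordinate 4th-order Fourier fit of the annular points
## -> best-fit-plane projection -> perimeters (L2D/L3D), areas (A2D/A3D),
## centroid chords (Dmax/Dmin) -> Delaunay leaflet surface -> tenting
## volume. All lengths mm, areas mm^2, volumes mL.

#' Define the valve long axis from landmarks
#'
#' @param landmarks an [annulus_landmarks()] set.
#' @param mode `"from_annulus"` (total-least-squares normal of the annular
#'   points, oriented toward the ventricle, i.e. toward the mean free-margin
#'   offset) or `"from_annotation"` (take the axis stored in the annotation).
#' @return An object of class `long_axis`: list with `origin` (annular
#'   centroid, mm) and unit `direction` (ventricular).
#' @export
define_long_axis <- function(landmarks, mode = c("from_annulus", "from_annotation")) {
  stopifnot(inherits(landmarks, "annulus_landmarks"))
  mode <- match.arg(mode)
  if (mode == "from_annotation") {
    if (is.null(landmarks$axis))
      stop_trimorph("annotation carries no long-axis record", "trimorph_invalid_parameter")
    ax <- landmarks$axis
    return(structure(list(origin = as.numeric(ax$origin),
                          direction = unit(as.numeric(ax$direction))),
                     class = "long_axis"))
  }
  pts <- landmarks$annular
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2L, ctr)
  sv <- svd(cen)
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop_trimorph("annular points are collinear", "trimorph_degenerate_geometry")
  nrm <- sv$v[, 3L]
  tent <- colMeans(landmarks$free_margin) - ctr    # leaflets tent ventricularly
  if (sum(nrm * tent) < 0) nrm <- -nrm
  structure(list(origin = ctr, direction = unit(nrm)), class = "long_axis")
}

#' Generate the 18 rotated measurement half-planes
#'
#' Half-planes through the long axis at azimuths `k * 20` degrees,
#' k = 0..17; opposite stations (k, k + 9) form one diametric image plane.
#'
#' @param axis a `long_axis`.
#' @return An object of class `rotation_planes`: list with `angles_deg`,
#'   `directions` (18 x 3 in-plane unit radial directions), `axis`, and the
#'   frame vectors `e1`, `e2`.
#' @export
generate_planes <- function(axis) {
  stopifnot(inherits(axis, "long_axis"))
  b <- plane_basis(axis$direction)
  ang <- seq(0, 340, by = STATION_STEP_DEG)
  rad <- ang * pi / 180
  dirs <- outer(cos(rad), b$e1) + outer(sin(rad), b$e2)
  structure(list(angles_deg = ang, directions = dirs, axis = axis,
                 e1 = b$e1, e2 = b$e2),
            class = "rotation_planes")
}

#' Ingest landmarks from an annotation file, landmark set, or phantom
#'
#' @param x an annotation JSON path, an [annulus_landmarks()] set (returned
#'   unchanged), or a [leaflet_spec()] (ground-truth landmarks are sampled
#'   from the phantom).
#' @param ... passed to [phantom_landmarks()] in phantom mode.
#' @return An [annulus_landmarks()] set in world coordinates (mm).
#' @export
extract_landmarks <- function(x, ...) {
  if (inherits(x, "annulus_landmarks")) return(x)
  if (inherits(x, "leaflet_spec")) return(phantom_landmarks(x, ...))
  if (is.character(x) && length(x) == 1L) return(read_annotation(x))
  stop_trimorph("cannot extract landmarks from this input", "trimorph_invalid_parameter")
}

#' Fit a Fourier annulus to annular landmarks
#'
#' Per-coordinate linear least squares on the harmonic basis
#' `{1, cos k phi, sin k phi}`, k = 1..order, with phi the station azimuth.
#' With 18 stations and order 4 the system is overdetermined (18 equations,
#' 9 unknowns per coordinate); curves of harmonic content <= order sampled
#' exactly are reproduced to machine precision.
#'
#' @param landmarks an [annulus_landmarks()] set.
#' @param order Fourier order (default 4).
#' @param n_poly number of points of the sampled polyline.
#' @return An object of class `fitted_annulus`: list with `model` (an
#'   [annulus_model()]), `polyline` (`n_poly` x 3, closed implicitly),
#'   `centroid`, `residual_rms` (mm) and `axis` (a `long_axis`).
#' @export
fit_annulus <- function(landmarks, order = 4L, n_poly = 360L) {
  stopifnot(inherits(landmarks, "annulus_landmarks"))
  n_st <- length(landmarks$angles_deg)
  if (n_st < 2L * order + 1L)
    stop_trimorph(sprintf("%d stations cannot determine a Fourier fit of order %d",
                          n_st, order), "trimorph_underdetermined")
  phi <- landmarks$angles_deg * pi / 180
  k <- seq_len(order)
  X <- cbind(1, cos(outer(phi, k)), sin(outer(phi, k)))
  beta <- qr.solve(X, landmarks$annular)          # (2 order + 1) x 3
  a <- t(rbind(beta[1L, , drop = FALSE], beta[1L + k, , drop = FALSE]))
  b <- t(rbind(0, beta[1L + order + k, , drop = FALSE]))
  axis <- define_long_axis(landmarks)
  model <- annulus_model(a, b, axis_origin = axis$origin,
                         axis_direction = axis$direction)
  resid <- landmarks$annular - X %*% beta
  th <- seq(0, 2 * pi, length.out = n_poly + 1L)[-(n_poly + 1L)]
  poly <- annulus_eval(model, th)
  ## the reference annular plane is fitted to an arc-length-uniform
  ## resampling of the curve, so it does not depend on how the curve
  ## happens to be parameterized
  plane <- best_fit_plane(resample_closed_curve(annulus_eval(
    model, seq(0, 2 * pi, length.out = 1441L)[-1441L]), 720L),
    orient = axis)
  structure(list(model = model, polyline = poly,
                 centroid = as.numeric(a[, 1L]),
                 residual_rms = sqrt(mean(rowSums(resid^2))),
                 axis = axis, plane = plane),
            class = "fitted_annulus")
}

#' Total-least-squares plane through 3D points
#'
#' The plane through the centroid whose normal is the smallest principal
#' component of the centered points. When `orient` (a `long_axis` or a
#' 3-vector pointing ventricularly) is given, the normal is flipped to point
#' atrially (against it), the convention the tenting volume expects.
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @param orient optional ventricular reference direction.
#' @return An object of class `best_fit_plane`: list with `point`, unit
#'   `normal`, and the in-plane basis `e1`, `e2`.
#' @export
best_fit_plane <- function(points, orient = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop_trimorph("need at least 3 points", "trimorph_degenerate_geometry")
  ctr <- colMeans(points)
  cen <- sweep(points, 2L, ctr)
  sv <- svd(cen)
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop_trimorph("points are collinear", "trimorph_degenerate_geometry")
  nrm <- sv$v[, 3L]
  if (!is.null(orient)) {
    dir <- if (inherits(orient, "long_axis")) orient$direction else orient
    if (sum(nrm * dir) > 0) nrm <- -nrm           # atrial normal
  }
  b <- plane_basis(nrm)
  structure(list(point = ctr, normal = nrm, e1 = b$e1, e2 = b$e2),
            class = "best_fit_plane")
}

## Resample a closed polyline at n points uniform in arc length.
resample_closed_curve <- function(poly, n = 720L) {
  closed <- rbind(poly, poly[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(s, closed[, 1L], xout = target)$y,
        stats::approx(s, closed[, 2L], xout = target)$y,
        stats::approx(s, closed[, 3L], xout = target)$y)
}

project_to_plane <- function(points, plane) {
  rel <- sweep(as.matrix(points), 2L, plane$point)
  cbind(u = as.numeric(rel %*% plane$e1), v = as.numeric(rel %*% plane$e2))
}

closed_arclength <- function(pts) {
  nxt <- pts[c(2:nrow(pts), 1L), , drop = FALSE]
  sum(sqrt(rowSums((nxt - pts)^2)))
}

#' Annulus perimeters on the 3D curve and its planar projection
#'
#' @param fitted a `fitted_annulus`.
#' @param plane a `best_fit_plane` (defaults to the fit's own plane).
#' @return list with `L2D` and `L3D`, mm.
#' @export
compute_perimeters <- function(fitted, plane = NULL) {
  stopifnot(inherits(fitted, "fitted_annulus"))
  plane <- plane %||% fitted$plane
  L3D <- closed_arclength(fitted$polyline)
  L2D <- closed_arclength(project_to_plane(fitted$polyline, plane))
  list(L2D = L2D, L3D = L3D)
}

## polar radius of a centered closed polyline; errors if not star-shaped
polar_profile <- function(uv) {
  az <- atan2(uv[, 2L], uv[, 1L]) %% (2 * pi)
  r <- sqrt(rowSums(uv^2))
  if (any(r < 1e-9))
    stop_trimorph("curve passes through its own centroid", "trimorph_non_star_shaped")
  d <- diff(c(az, az[1L]))
  d <- (d + pi) %% (2 * pi) - pi
  if (sum(d) < 0) d <- -d                  # clockwise traversal is fine too
  if (any(d <= 0))
    stop_trimorph("projected curve is not star-shaped about the centroid",
                  "trimorph_non_star_shaped")
  ord <- order(az)
  list(az = az[ord], r = r[ord])
}

#' Annulus areas on the planar projection and the 3D profile
#'
#' `A2D` is the shoelace area of the projected polygon; `A3D` is the area of
#' the triangle fan from the 3D centroid over the 3D polyline (the minimal
#' standard reading of the area "enclosed by" a non-planar curve; it reduces
#' to `A2D` for planar curves).
#'
#' @inheritParams compute_perimeters
#' @return list with `A2D` and `A3D`, mm^2.
#' @export
compute_areas <- function(fitted, plane = NULL) {
  stopifnot(inherits(fitted, "fitted_annulus"))
  plane <- plane %||% fitted$plane
  uv <- project_to_plane(fitted$polyline, plane)
  ## star-shapedness about the centroid guarantees a simple polygon
  polar_profile(sweep(uv, 2L, colMeans(uv)))
  A2D <- shoelace_area(uv)
  p <- fitted$polyline
  ctr <- colMeans(p)
  r1 <- sweep(p, 2L, ctr)
  r2 <- r1[c(2:nrow(p), 1L), , drop = FALSE]
  cr <- cbind(r1[, 2L] * r2[, 3L] - r1[, 3L] * r2[, 2L],
              r1[, 3L] * r2[, 1L] - r1[, 1L] * r2[, 3L],
              r1[, 1L] * r2[, 2L] - r1[, 2L] * r2[, 1L])
  A3D <- sum(sqrt(rowSums(cr^2))) / 2
  list(A2D = A2D, A3D = A3D)
}

#' Extremal annular chords through the centroid
#'
#' For a dense set of directions from the projected annular centroid, the
#' chord is the segment joining the two crossings of the centroid line with
#' the projected annulus; `Dmax`/`Dmin` are its extremes. The direction grid
#' is 0.05 degrees, finer than a 1-degree scan with 0.1-degree refinement.
#'
#' @inheritParams compute_perimeters
#' @return list with `Dmax` and `Dmin`, mm.
#' @export
compute_diameters <- function(fitted, plane = NULL) {
  stopifnot(inherits(fitted, "fitted_annulus"))
  plane <- plane %||% fitted$plane
  n_dense <- 7200L
  th <- seq(0, 2 * pi, length.out = n_dense + 1L)[-(n_dense + 1L)]
  uv <- project_to_plane(annulus_eval(fitted$model, th), plane)
  ctr <- project_to_plane(matrix(fitted$centroid, 1L), plane)
  pp <- polar_profile(sweep(uv, 2L, as.numeric(ctr)))
  az_ext <- c(pp$az - 2 * pi, pp$az, pp$az + 2 * pi)
  r_ext <- c(pp$r, pp$r, pp$r)
  rfun <- stats::approxfun(az_ext, r_ext)
  phi <- seq(0, pi, by = pi / 3600)
  chord <- rfun(phi) + rfun(phi + pi)
  list(Dmax = max(chord), Dmin = min(chord))
}

## Harmonic (trigonometric) azimuthal interpolation of an 18-point ring:
## per-coordinate least squares on {1, cos k phi, sin k phi}, k = 1..8,
## evaluated on a finer azimuth grid. Exact for rings of harmonic content
## <= 8, which covers every supported phantom.
refine_ring <- function(ring, angles_deg, n_out = 72L) {
  phi <- angles_deg * pi / 180
  k <- 1:8
  X <- cbind(1, cos(outer(phi, k)), sin(outer(phi, k)))
  beta <- qr.solve(X, ring)
  phi_out <- seq(0, 2 * pi, length.out = n_out + 1L)[-(n_out + 1L)]
  Xo <- cbind(1, cos(outer(phi_out, k)), sin(outer(phi_out, k)))
  Xo %*% beta
}

#' Reconstruct the leaflet surface by Delaunay triangulation
#'
#' All available surface points (annulus polyline, free-margin points,
#' leaflet traces, coaptation apex) are projected onto the best-fit plane,
#' triangulated in 2D, lifted back to 3D, and triangles falling outside the
#' projected annulus polygon are discarded. The projection step encodes the
#' single-valued-surface assumption of a closed valve. Because interior
#' points exist only on the 18 annotation planes, each ring of homologous
#' trace points (and the free-margin ring) is first azimuthally refined by
#' harmonic interpolation; without this the mesh's 20-degree azimuthal gaps
#' bias the tenting volume by several percent.
#'
#' @param landmarks an [annulus_landmarks()] set.
#' @param fitted a `fitted_annulus`.
#' @param plane a `best_fit_plane` (defaults to the fit's own plane).
#' @param annulus_step take every `annulus_step`-th polyline vertex as a
#'   mesh boundary vertex.
#' @param refine azimuthal points per interpolated ring (0 disables
#'   refinement and triangulates the raw landmarks).
#' @return An object of class `leaflet_mesh`: list with `vertices` (n x 3),
#'   `triangles` (m x 3 indices), `vertices_2d`.
#' @export
reconstruct_leaflet_surface <- function(landmarks, fitted, plane = NULL,
                                        annulus_step = 5L, refine = 72L) {
  stopifnot(inherits(landmarks, "annulus_landmarks"),
            inherits(fitted, "fitted_annulus"))
  plane <- plane %||% fitted$plane
  ring <- fitted$polyline[seq(1L, nrow(fitted$polyline), by = annulus_step), ,
                          drop = FALSE]
  tr <- landmarks$traces
  uniform_traces <- !is.null(tr) &&
    length(unique(vapply(tr, nrow, 0L))) == 1L
  if (refine > 0L) {
    inner <- list(refine_ring(landmarks$free_margin, landmarks$angles_deg,
                              refine))
    if (uniform_traces) {
      for (j in seq_len(nrow(tr[[1L]]))) {
        ring_j <- do.call(rbind, lapply(tr, function(m) m[j, ]))
        inner[[length(inner) + 1L]] <- refine_ring(ring_j,
                                                   landmarks$angles_deg, refine)
      }
    } else if (!is.null(tr)) {
      inner[[length(inner) + 1L]] <- do.call(rbind, tr)
    }
    interior <- do.call(rbind, inner)
  } else {
    interior <- rbind(landmarks$free_margin,
                      if (!is.null(tr)) do.call(rbind, tr))
  }
  pts <- rbind(ring, interior,
               if (!is.null(landmarks$apex)) matrix(landmarks$apex, 1L))
  if (nrow(pts) < 3L)
    stop_trimorph("need at least 3 surface points", "trimorph_invalid_parameter")
  uv <- project_to_plane(pts, plane)
  keep <- !duplicated(round(uv / 1e-6))           # voxel snapping can collide
  pts <- pts[keep, , drop = FALSE]
  uv <- uv[keep, , drop = FALSE]
  tri <- delaunay2d(uv)
  ring_uv <- project_to_plane(fitted$polyline, plane)
  cent <- (uv[tri[, 1L], ] + uv[tri[, 2L], ] + uv[tri[, 3L], ]) / 3
  inside <- points_in_polygon(cent, ring_uv)
  a2 <- abs((uv[tri[, 2L], 1L] - uv[tri[, 1L], 1L]) *
              (uv[tri[, 3L], 2L] - uv[tri[, 1L], 2L]) -
            (uv[tri[, 3L], 1L] - uv[tri[, 1L], 1L]) *
              (uv[tri[, 2L], 2L] - uv[tri[, 1L], 2L]))
  tri <- tri[inside & a2 > 1e-9, , drop = FALSE]
  structure(list(vertices = pts, triangles = tri, vertices_2d = uv,
                 plane = plane),
            class = "leaflet_mesh")
}

#' Tenting volume between the annular plane and the leaflet surface
#'
#' Sum over mesh triangles of the prism between the triangle and its
#' orthogonal projection on the plane, with vertex distances clipped at the
#' plane so only the ventricular side contributes (atrial prolapse cannot
#' cancel tenting).
#'
#' @param mesh a `leaflet_mesh`.
#' @param plane a `best_fit_plane` with atrial normal (defaults to the one
#'   stored in the mesh).
#' @return tenting volume, mL.
#' @export
tenting_volume <- function(mesh, plane = NULL) {
  stopifnot(inherits(mesh, "leaflet_mesh"))
  plane <- plane %||% mesh$plane
  s <- as.numeric(sweep(mesh$vertices, 2L, plane$point) %*% plane$normal)
  depth <- pmax(0, -s)                            # ventricular side only
  uv <- project_to_plane(mesh$vertices, plane)
  tri <- mesh$triangles
  a_proj <- abs((uv[tri[, 2L], 1L] - uv[tri[, 1L], 1L]) *
                  (uv[tri[, 3L], 2L] - uv[tri[, 1L], 2L]) -
                (uv[tri[, 3L], 1L] - uv[tri[, 1L], 1L]) *
                  (uv[tri[, 2L], 2L] - uv[tri[, 1L], 2L])) / 2
  mean_depth <- (depth[tri[, 1L]] + depth[tri[, 2L]] + depth[tri[, 3L]]) / 3
  sum(a_proj * mean_depth) / 1000
}

#' Run the full morphometric pipeline
#'
#' Composes landmark ingestion, long-axis definition, Fourier fitting,
#' best-fit-plane projection, perimeter/area/diameter computation, leaflet
#' surface reconstruction and tenting volume.
#'
#' @param x input accepted by [extract_landmarks()]: annotation path,
#'   landmark set, or valve phantom ([leaflet_spec()]).
#' @param order Fourier order of the annulus fit.
#' @return An object of class `morpho_result`: list with `L2D`, `L3D`,
#'   `A2D`, `A3D` (mm, mm^2), `Dmax`, `Dmin` (mm), `Tvol` (mL),
#'   `residual_rms`, and a `provenance` block (input hash).
#' @export
run_morphometry <- function(x, order = 4L) {
  lm <- extract_landmarks(x)
  fitted <- fit_annulus(lm, order = order)
  plane <- fitted$plane
  per <- compute_perimeters(fitted, plane)
  ar <- compute_areas(fitted, plane)
  di <- compute_diameters(fitted, plane)
  mesh <- reconstruct_leaflet_surface(lm, fitted, plane)
  tvol <- tenting_volume(mesh, plane)
  res <- list(L2D = per$L2D, L3D = per$L3D, A2D = ar$A2D, A3D = ar$A3D,
              Dmax = di$Dmax, Dmin = di$Dmin, Tvol = tvol,
              residual_rms = fitted$residual_rms,
              provenance = list(
                input_hash = config_hash(list(annular = round(lm$annular, 9),
                                              order = order)),
                order = order))
  class(res) <- "morpho_result"
  res
}

#' @export
print.morpho_result <- function(x, ...) {
  cat(sprintf(paste0("<morpho_result>\n  L2D %.2f mm   L3D %.2f mm\n",
                     "  A2D %.1f mm^2  A3D %.1f mm^2\n",
                     "  Dmax %.2f mm  Dmin %.2f mm\n  Tvol %.3f mL\n"),
              x$L2D, x$L3D, x$A2D, x$A3D, x$Dmax, x$Dmin, x$Tvol))
  invisible(x)
}
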