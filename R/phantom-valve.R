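## Parametric tricuspid-valve phantoms.
##
## The leaflet surface is a single-valued tent over the annulus: for radial
## fraction f in [0, 1] (f = 1 on the annulus, f = 0 at the coaptation
## center) and sweep angle theta,
##   S(f, theta) = c + f (Q(theta) - c) + [ f d(theta) + h g(f) ] n
## where Q is the annulus projected on the phantom plane through its centroid
## c with ventricular unit normal n, d is the annulus' out-of-plane offset,
## h the tenting depth and g the tenting profile (paraboloid 1 - f^2, cone
## 1 - f, flat 0). Leaflets tent toward the ventricle (+n).

#' Leaflet phantom specification
#'
#' @param annulus an [annulus_model()].
#' @param tenting_profile `"paraboloid"`, `"cone"` or `"flat"`.
#' @param tenting_depth apex depth h below the annular plane, mm; must be 0
#'   for the flat profile.
#' @param commissure_angles azimuths (radians) of the commissures; default
#'   three leaflets. Decorative metadata only: the surface is single-valued.
#' @param free_margin_fraction fraction of the annulus-to-center distance
#'   covered by the leaflet body; the free-margin landmark sits at radial
#'   fraction `1 - free_margin_fraction`.
#' @return An object of class `leaflet_spec`.
#' @export
leaflet_spec <- function(annulus,
                         tenting_profile = c("paraboloid", "cone", "flat"),
                         tenting_depth = 7,
                         commissure_angles = c(0, 2, 4) * pi / 3,
                         free_margin_fraction = 0.6) {
  stopifnot(inherits(annulus, "annulus_model"))
  tenting_profile <- match.arg(tenting_profile)
  assert_scalar_num(tenting_depth, "tenting_depth", nonneg = TRUE)
  if (tenting_profile == "flat" && tenting_depth > 0)
    stop_trimorph("flat tenting profile requires tenting_depth = 0",
                  "trimorph_inconsistent_spec")
  if (free_margin_fraction <= 0 || free_margin_fraction > 1)
    stop_trimorph("free_margin_fraction must be in (0, 1]", "trimorph_invalid_parameter")
  structure(list(annulus = annulus, tenting_profile = tenting_profile,
                 tenting_depth = tenting_depth,
                 commissure_angles = commissure_angles,
                 free_margin_fraction = free_margin_fraction),
            class = "leaflet_spec")
}

tenting_g <- function(profile, f) {
  switch(profile,
         paraboloid = 1 - f^2,
         cone       = 1 - f,
         flat       = rep(0, length(f)))
}

## Evaluate the leaflet surface at radial fractions f and angles theta
## (same length, element-wise). Returns n x 3 matrix, mm.
leaflet_surface <- function(spec, f, theta) {
  ann <- spec$annulus
  n <- ann$axis_direction
  c0 <- ann$a[, 1L]                      # Fourier mean = curve centroid
  p <- annulus_eval(ann, theta)
  rel <- sweep(p, 2L, c0)
  d <- as.numeric(rel %*% n)
  q_rel <- rel - outer(d, n)             # in-plane part of (P - c)
  h <- spec$tenting_depth
  off <- f * d + h * tenting_g(spec$tenting_profile, f)
  sweep(q_rel * f + outer(off, n), 2L, c0, "+")
}

## Oracle-side best-fit plane: smallest eigenvector of the (weighted) point
## covariance, normal oriented atrially (against the ventricular axis).
## Weights are the local curve speed |P'|, making the plane an arc-length
## functional of the curve, invariant to reparameterization — the same
## continuum plane the measurement pipeline approaches when it fits its
## arc-length-resampled polyline. Kept separate from the pipeline's
## best_fit_plane on purpose.
oracle_plane <- function(pts, ventricular, weights = NULL) {
  w <- weights %||% rep(1, nrow(pts))
  w <- w / sum(w)
  ctr <- colSums(pts * w)
  cen <- sweep(pts, 2L, ctr)
  ev <- eigen(crossprod(cen, cen * w), symmetric = TRUE)
  nrm <- ev$vectors[, 3L]
  if (sum(nrm * ventricular) > 0) nrm <- -nrm
  list(point = ctr, normal = nrm)
}

#' Closed-form/quadrature ground truth for a valve phantom
#'
#' Computes every morphometric metric by dense quadrature directly on the
#' parametric annulus and leaflet surface, independent of the measurement
#' pipeline (no Fourier fitting, no Delaunay meshing). Serves as the oracle
#' that the image-style pipeline is tested against.
#'
#' @param annulus an [annulus_model()].
#' @param leaflets a [leaflet_spec()], or `NULL` to skip the tenting volume.
#' @param n_quad number of quadrature nodes along the curve (>= 1e4).
#' @return list with `L2D`, `L3D` (mm), `A2D`, `A3D` (mm^2), `Dmax`, `Dmin`
#'   (mm) and `Tvol` (mL; `NA` if `leaflets` is `NULL`).
#' @export
analytic_truth <- function(annulus, leaflets = NULL, n_quad = 1e5) {
  stopifnot(inherits(annulus, "annulus_model"))
  if (n_quad < 1e4)
    stop_trimorph("n_quad must be >= 1e4", "trimorph_invalid_parameter")
  n_quad <- as.integer(n_quad)
  th <- seq(0, 2 * pi, length.out = n_quad + 1L)[-(n_quad + 1L)]
  p <- annulus_eval(annulus, th)
  dp <- annulus_eval(annulus, th, deriv = 1L)
  dth <- 2 * pi / n_quad

  speed <- sqrt(rowSums(dp^2))
  L3D <- sum(speed) * dth

  pl <- oracle_plane(p, annulus$axis_direction, weights = speed)
  nrm <- pl$normal
  basis <- plane_basis(nrm)
  rel <- sweep(p, 2L, pl$point)
  d <- as.numeric(rel %*% nrm)
  u <- as.numeric(rel %*% basis$e1)
  v <- as.numeric(rel %*% basis$e2)
  du <- as.numeric(dp %*% basis$e1)
  dv <- as.numeric(dp %*% basis$e2)
  L2D <- sum(sqrt(du^2 + dv^2)) * dth
  A2D <- abs(sum(u * dv - v * du)) * dth / 2   # Green's theorem

  ctr3 <- colMeans(p)
  r1 <- sweep(p, 2L, ctr3)
  r2 <- r1[c(2:n_quad, 1L), ]
  cr <- cbind(r1[, 2L] * r2[, 3L] - r1[, 3L] * r2[, 2L],
              r1[, 3L] * r2[, 1L] - r1[, 1L] * r2[, 3L],
              r1[, 1L] * r2[, 2L] - r1[, 2L] * r2[, 1L])
  A3D <- sum(sqrt(rowSums(cr^2))) / 2

  ## chords through the projected centroid, polar representation
  uc <- u - mean(u); vc <- v - mean(v)
  az <- atan2(vc, uc) %% (2 * pi)
  rr <- sqrt(uc^2 + vc^2)
  ord <- order(az)
  az_s <- az[ord]; rr_s <- rr[ord]
  az_ext <- c(az_s - 2 * pi, az_s, az_s + 2 * pi)
  rr_ext <- c(rr_s, rr_s, rr_s)
  phi <- seq(0, pi, by = pi / 18000)
  rfun <- stats::approxfun(az_ext, rr_ext)
  chord <- rfun(phi) + rfun(phi + pi)
  Dmax <- max(chord); Dmin <- min(chord)

  Tvol <- if (!is.null(leaflets))
    oracle_tenting_volume(annulus, leaflets, plane = pl) else NA_real_
  list(L2D = L2D, L3D = L3D, A2D = A2D, A3D = A3D,
       Dmax = Dmax, Dmin = Dmin, Tvol = Tvol)
}

## Quadrature of the clipped depth below the arc-length best-fit plane.
## The surface S(f, theta) = c0 + f (Q - c0) + [f d + h g(f)] n_v has
## analytic tangents dS/dtheta = f P'(theta) and
## dS/df = (P - c0) + h g'(f) n_v, so the area element of its projection
## onto the plane is the 2x2 Jacobian of the projected tangents.
oracle_tenting_volume <- function(annulus, leaflets, plane = NULL,
                                  n_t = 1024L, n_f = 256L) {
  stopifnot(inherits(leaflets, "leaflet_spec"))
  if (leaflets$tenting_profile == "flat" && leaflets$tenting_depth > 0)
    stop_trimorph("flat profile with positive depth", "trimorph_inconsistent_spec")
  if (is.null(plane)) {
    thp <- seq(0, 2 * pi, length.out = 8193L)[-8193L]
    pp <- annulus_eval(annulus, thp)
    spd <- sqrt(rowSums(annulus_eval(annulus, thp, deriv = 1L)^2))
    plane <- oracle_plane(pp, annulus$axis_direction, weights = spd)
  }
  nrm <- plane$normal
  basis <- plane_basis(nrm)
  th_m <- (seq_len(n_t) - 0.5) * 2 * pi / n_t
  f_m <- (seq_len(n_f) - 0.5) / n_f
  n_v <- annulus$axis_direction
  c0 <- annulus$a[, 1L]
  h <- leaflets$tenting_depth
  g <- tenting_g(leaflets$tenting_profile, f_m)
  gp <- switch(leaflets$tenting_profile,
               paraboloid = -2 * f_m, cone = rep(-1, n_f),
               flat = rep(0, n_f))
  pm <- annulus_eval(annulus, th_m)
  dpm <- annulus_eval(annulus, th_m, deriv = 1L)
  relm <- sweep(pm, 2L, c0)                    # P - c0, n_t x 3
  d_off <- as.numeric(relm %*% n_v)
  e1 <- basis$e1; e2 <- basis$e2
  rel_u <- as.numeric(relm %*% e1); rel_v <- as.numeric(relm %*% e2)
  rel_n <- as.numeric(relm %*% nrm)
  dp_u <- as.numeric(dpm %*% e1); dp_v <- as.numeric(dpm %*% e2)
  nv_u <- sum(n_v * e1); nv_v <- sum(n_v * e2); nv_n <- sum(n_v * nrm)
  c0_n <- sum((c0 - plane$point) * nrm)
  F <- matrix(f_m, n_f, n_t)
  G <- matrix(g, n_f, n_t)
  GP <- matrix(gp, n_f, n_t)
  D <- matrix(d_off, n_f, n_t, byrow = TRUE)
  ## signed atrial height of S relative to the plane:
  ## (S - p0).n = c0_n + f [(P - c0).n - d (n_v.n)] + (f d + h g)(n_v.n)
  S_n <- c0_n + F * matrix(rel_n - d_off * nv_n, n_f, n_t, byrow = TRUE) +
    (F * D + h * G) * nv_n
  depth <- pmax(0, -S_n)
  ## projected tangents: dS/dtheta = f P', dS/df = (P - c0) + h g'(f) n_v
  Tu <- F * matrix(dp_u, n_f, n_t, byrow = TRUE)
  Tv <- F * matrix(dp_v, n_f, n_t, byrow = TRUE)
  Fu <- matrix(rel_u, n_f, n_t, byrow = TRUE) + h * GP * nv_u
  Fv <- matrix(rel_v, n_f, n_t, byrow = TRUE) + h * GP * nv_v
  jac <- abs(Fu * Tv - Fv * Tu)
  sum(depth * jac) * (1 / n_f) * (2 * pi / n_t) / 1000
}
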