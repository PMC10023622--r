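## Fourier-form annulus curves.
##
## An annulus is a closed 3D curve written per coordinate as a truncated
## Fourier series in the sweep angle theta:
##   P_c(theta) = sum_{k=0}^{order} a_{c,k} cos(k theta) + b_{c,k} sin(k theta)
## This single form carries both the phantom ground truth and the result of
## fitting manually picked annular points, so every geometric routine works
## on either without conversion.

#' Construct an annulus model
#'
#' @param a,b 3 x (order+1) coefficient matrices (rows x, y, z; column k+1
#'   holds the order-k cosine/sine coefficient, mm). The k = 0 sine column is
#'   forced to zero.
#' @param axis_origin 3-vector, mm. Typically the curve centroid.
#' @param axis_direction unit 3-vector; by convention it points from the
#'   annulus toward the ventricle (the side the leaflets tent to).
#' @return An object of class `annulus_model`.
#' @export
annulus_model <- function(a, b, axis_origin = c(0, 0, 0),
                          axis_direction = c(0, 0, 1)) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || nrow(a) != 3L)
    stop_trimorph("coefficient matrices must both be 3 x (order+1)",
                  "trimorph_invalid_parameter")
  b[, 1L] <- 0
  if (abs(vnorm(axis_direction) - 1) > 1e-9)
    stop_trimorph("axis_direction must have unit norm", "trimorph_invalid_parameter")
  structure(list(order = ncol(a) - 1L, a = a, b = b,
                 axis_origin = as.numeric(axis_origin),
                 axis_direction = as.numeric(axis_direction)),
            class = "annulus_model")
}

#' @export
print.annulus_model <- function(x, ...) {
  cat(sprintf("<annulus_model> Fourier order %d, centroid (%.2f, %.2f, %.2f) mm\n",
              x$order, x$a[1L, 1L], x$a[2L, 1L], x$a[3L, 1L]))
  invisible(x)
}

#' Evaluate an annulus curve (or its derivative) at angles theta
#'
#' @param model an [annulus_model()].
#' @param theta numeric vector of angles, radians.
#' @param deriv 0 for position, 1 for d/dtheta.
#' @return length(theta) x 3 matrix, mm (or mm/rad).
#' @export
annulus_eval <- function(model, theta, deriv = 0L) {
  k <- 0:model$order
  kt <- outer(theta, k)                     # n x (order+1)
  if (deriv == 0L) {
    basis_c <- cos(kt); basis_s <- sin(kt)
    out <- basis_c %*% t(model$a) + basis_s %*% t(model$b)
  } else {
    km <- matrix(k, nrow = length(theta), ncol = length(k), byrow = TRUE)
    out <- (-sin(kt) * km) %*% t(model$a) + (cos(kt) * km) %*% t(model$b)
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Build a parametric annulus phantom
#'
#' Three canonical shapes, all returned in Fourier form:
#' * `circle`: radius `r`, in the z = 0 plane.
#' * `ellipse`: semi-axes `a_mm` (x) and `b_mm` (y), planar.
#' * `saddle`: the ellipse plus the classic bimodal out-of-plane term
#'   `z = saddle_height * cos(2 theta)` (two highs, two lows per revolution).
#'
#' @param kind `"circle"`, `"ellipse"` or `"saddle"`.
#' @param r circle radius, mm.
#' @param a_mm,b_mm ellipse/saddle semi-axes, mm.
#' @param saddle_height amplitude of the `cos(2 theta)` out-of-plane term, mm.
#' @param center 3-vector, mm.
#' @return An [annulus_model()] with `axis_direction = c(0, 0, 1)` (the
#'   ventricular side of the phantom is +z).
#' @export
#' @examples
#' ann <- build_annulus("saddle", a_mm = 25.1, b_mm = 21.55, saddle_height = 3.6)
build_annulus <- function(kind = c("circle", "ellipse", "saddle"),
                          r = 20, a_mm = r, b_mm = r, saddle_height = 5,
                          center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  if (kind == "circle") { a_mm <- r; b_mm <- r }
  assert_scalar_num(a_mm, "a_mm", positive = TRUE)
  assert_scalar_num(b_mm, "b_mm", positive = TRUE)
  order <- 4L
  a <- matrix(0, 3L, order + 1L); b <- matrix(0, 3L, order + 1L)
  a[1L, 2L] <- a_mm                         # x = a cos(theta)
  b[2L, 2L] <- b_mm                         # y = b sin(theta)
  if (kind == "saddle") {
    assert_scalar_num(saddle_height, "saddle_height", nonneg = TRUE)
    a[3L, 3L] <- saddle_height              # z = h cos(2 theta)
  }
  a[, 1L] <- a[, 1L] + center
  annulus_model(a, b, axis_origin = center, axis_direction = c(0, 0, 1))
}

## Invert the azimuth map of a curve: find theta values at which the curve,
## projected onto the axis frame, sits at the requested azimuths (radians,
## measured from e1 toward e2 about axis_direction). Used to place landmark
## stations at exactly k * 20 degrees.
annulus_theta_at_azimuth <- function(model, azimuths, n_dense = 4096L) {
  basis <- plane_basis(model$axis_direction)
  th <- seq(0, 2 * pi, length.out = n_dense + 1L)[-(n_dense + 1L)]
  p <- annulus_eval(model, th)
  rel <- sweep(p, 2L, model$axis_origin)
  u <- rel %*% basis$e1
  v <- rel %*% basis$e2
  az <- atan2(v, u) %% (2 * pi)
  target <- azimuths
  d <- diff(c(az, az[1L]))
  d <- (d + pi) %% (2 * pi) - pi
  if (sum(d) < 0) {
    ## clockwise parameterization: mirror the azimuth axis and targets
    az <- (-az) %% (2 * pi)
    target <- (-target) %% (2 * pi)
    d <- -d
  }
  if (any(d <= 0))
    stop_trimorph("curve is not star-shaped about its axis origin",
                  "trimorph_non_star_shaped")
  ## unwrap to a monotone sequence starting at az[1]
  az_un <- az[1L] + cumsum(c(0, d[-length(d)]))
  th_ext <- c(th, th[1L] + 2 * pi)
  az_ext <- c(az_un, az_un[1L] + 2 * pi)
  target <- (target - az_ext[1L]) %% (2 * pi) + az_ext[1L]
  stats::approx(az_ext, th_ext, xout = target, rule = 2L)$y %% (2 * pi)
}
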