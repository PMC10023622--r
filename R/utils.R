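## Small shared numerical helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_trimorph <- function(msg, class, ...) {
  stop(structure(class = c(class, "trimorph_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_trimorph(sprintf("`%s` must be a finite numeric scalar", name),
                  "trimorph_invalid_parameter")
  if (positive && x <= 0)
    stop_trimorph(sprintf("`%s` must be > 0 (got %g)", name, x),
                  "trimorph_invalid_parameter")
  if (nonneg && x < 0)
    stop_trimorph(sprintf("`%s` must be >= 0 (got %g)", name, x),
                  "trimorph_invalid_parameter")
  invisible(x)
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12)
    stop_trimorph("cannot normalize a near-zero vector", "trimorph_degenerate_geometry")
  v / n
}

## Trapezoidal integral of y over uniform grid with step dt.
trapz <- function(y, dt) dt * (sum(y) - 0.5 * (y[1L] + y[length(y)]))

## Periodic (wrap-around) trapezoid: exact for band-limited periodic signals.
trapz_periodic <- function(y, dt) dt * sum(y)

## Evaluate an expression with a private RNG stream (does not disturb the
## caller's .Random.seed).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Orthonormal in-plane basis {e1, e2} completing a unit normal to a
## right-handed frame. Deterministic: reference axis is the world axis least
## aligned with n.
plane_basis <- function(n) {
  n <- unit(n)
  ref <- diag(3)[, which.min(abs(n))]
  e1 <- unit(ref - sum(ref * n) * n)
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

## Shoelace area of a closed polygon given as an n x 2 matrix (not repeated).
shoelace_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

## Vectorized even-odd point-in-polygon test. pts: m x 2, poly: n x 2.
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  px <- poly[, 1L]; py <- poly[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(n)) {
    crosses <- ((py[i] > pts[, 2L]) != (qy[i] > pts[, 2L]))
    if (any(crosses)) {
      t <- (pts[crosses, 2L] - py[i]) / (qy[i] - py[i])
      xint <- px[i] + t * (qx[i] - px[i])
      flip <- pts[crosses, 1L] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  inside
}

## Stable md5 of an R object (via its canonical JSON form) for provenance.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}
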