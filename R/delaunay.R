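## 2D Delaunay triangulation by incremental insertion (Bowyer-Watson).
##
## Written for the leaflet-surface reconstruction: point sets are a few
## hundred projected landmarks, so an O(n^2) vectorized insertion loop is
## plenty fast and keeps the dependency surface at zero. Cocircular
## configurations (structured grids on circles are full of them) are
## resolved by a strict in-circle test with a relative tolerance; any of the
## admissible triangulations is acceptable downstream.

circumcircle <- function(p) {
  ax <- p[1L, 1L]; ay <- p[1L, 2L]
  bx <- p[2L, 1L]; by <- p[2L, 2L]
  cx <- p[3L, 1L]; cy <- p[3L, 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(c(NA_real_, NA_real_, Inf))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation of 2D points
#'
#' @param pts n x 2 numeric matrix; points must be pairwise distinct.
#' @return integer m x 3 matrix of triangle vertex indices into `pts`.
#' @export
delaunay2d <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L)
    stop_trimorph("need at least 3 points to triangulate", "trimorph_invalid_parameter")
  n <- nrow(pts)
  ctr <- colMeans(pts)
  scale <- max(apply(pts, 2L, function(x) diff(range(x))), 1e-9)
  P <- sweep(pts, 2L, ctr) / scale              # normalized copy
  eps <- 1e-12
  ## super-triangle well outside the unit-scale cloud
  P <- rbind(P, c(0, 40), c(-40, -30), c(40, -30))
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tri <- matrix(c(s1, s2, s3), 1L, 3L)
  cc <- matrix(circumcircle(P[c(s1, s2, s3), , drop = FALSE])[1:2], 1L, 2L)
  r2 <- circumcircle(P[c(s1, s2, s3), , drop = FALSE])[3L]
  for (i in seq_len(n)) {
    px <- P[i, 1L]; py <- P[i, 2L]
    bad <- (px - cc[, 1L])^2 + (py - cc[, 2L])^2 < r2 - eps
    if (!any(bad)) {
      ## on-circle degeneracy: fall back to containing-circle with <=
      bad <- (px - cc[, 1L])^2 + (py - cc[, 2L])^2 <= r2 + eps
    }
    bt <- tri[bad, , drop = FALSE]
    edges <- rbind(bt[, c(1L, 2L), drop = FALSE],
                   bt[, c(2L, 3L), drop = FALSE],
                   bt[, c(3L, 1L), drop = FALSE])
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    keep <- !(key %in% key[duplicated(key)])    # boundary = edges seen once
    poly <- edges[keep, , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    r2 <- r2[!bad]
    if (nrow(poly) > 0L) {
      newt <- cbind(rep(i, nrow(poly)), poly)
      newc <- t(apply(newt, 1L, function(tt)
        circumcircle(P[tt, , drop = FALSE])))
      ok <- is.finite(newc[, 3L])
      tri <- rbind(tri, newt[ok, , drop = FALSE])
      cc <- rbind(cc, newc[ok, 1:2, drop = FALSE])
      r2 <- c(r2, newc[ok, 3L])
    }
  }
  keep <- rowSums(tri > n) == 0L
  out <- tri[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  unname(out)
}
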