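## Shared fixtures: everything is generated in code, nothing on disk.

circle_phantom <- function(r = 20, profile = "paraboloid", h = 9.549) {
  leaflet_spec(build_annulus("circle", r = r), profile,
               tenting_depth = if (profile == "flat") 0 else h)
}

## Table-1-calibrated fresh ellipse (Dmax 50.2, Dmin 43.1)
calib_ellipse <- function() build_annulus("ellipse", a_mm = 25.1, b_mm = 21.55)

saddle_annulus <- function(height = 5)
  build_annulus("saddle", a_mm = 25.1, b_mm = 21.55, saddle_height = height)

## Apply a rigid motion to an annulus_model (Fourier coefficients transform
## linearly under rotation; only the k = 0 cosine column carries the shift).
rotate_annulus <- function(model, R, shift = c(0, 0, 0)) {
  a <- R %*% model$a
  b <- R %*% model$b
  a[, 1L] <- a[, 1L] + shift
  annulus_model(a, b,
                axis_origin = as.numeric(R %*% model$axis_origin + shift),
                axis_direction = as.numeric(R %*% model$axis_direction))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

apply_rigid_to_landmarks <- function(lm, R, shift) {
  tf <- function(m) sweep(as.matrix(m) %*% t(R), 2L, shift, "+")
  annulus_landmarks(tf(lm$annular), tf(lm$free_margin),
                    apm = if (!is.null(lm$apm)) as.numeric(tf(matrix(lm$apm, 1L))),
                    traces = if (!is.null(lm$traces)) lapply(lm$traces, tf),
                    apex = if (!is.null(lm$apex)) as.numeric(tf(matrix(lm$apex, 1L))),
                    axis = if (!is.null(lm$axis))
                      list(origin = as.numeric(R %*% lm$axis$origin + shift),
                           direction = as.numeric(R %*% lm$axis$direction)))
}

## Brute-force region-growing oracle: thresholded 6-connected component
## labeling by repeated dilation (tiny grids only).
cc_oracle <- function(speed_pos, seed_idx) {
  d <- dim(speed_pos)
  mask <- array(FALSE, d)
  mask[matrix(seed_idx, ncol = 3L)] <- TRUE
  repeat {
    grown <- mask
    shift_or <- function(m, ax, by) {
      out <- array(FALSE, d)
      idx_src <- lapply(d, seq_len); idx_dst <- idx_src
      if (by > 0) { idx_dst[[ax]] <- 2:d[ax]; idx_src[[ax]] <- 1:(d[ax] - 1) }
      else { idx_dst[[ax]] <- 1:(d[ax] - 1); idx_src[[ax]] <- 2:d[ax] }
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      out
    }
    for (ax in 1:3) for (by in c(-1, 1)) grown <- grown | shift_or(mask, ax, by)
    grown <- grown & speed_pos
    grown <- grown | mask
    if (identical(grown, mask)) break
    mask <- grown
  }
  mask
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
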