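test_that("define_long_axis finds the valve axis and respects equivariance", {
  lm <- phantom_landmarks(circle_phantom())
  ax <- define_long_axis(lm)
  expect_gt(abs(sum(ax$direction * c(0, 0, 1))), 1 - 1e-9)

  lm_up <- apply_rigid_to_landmarks(lm, diag(3), c(0, 0, 10))
  ax_up <- define_long_axis(lm_up)
  expect_equal(unname(ax_up$origin - ax$origin), c(0, 0, 10), tolerance = 1e-9)
  expect_equal(ax_up$direction, ax$direction, tolerance = 1e-12)

  ## saddle phantom: recovered axis within 1 degree of construction axis
  sad <- leaflet_spec(saddle_annulus(5), "paraboloid", tenting_depth = 7)
  ax_s <- define_long_axis(phantom_landmarks(sad))
  ang <- acos(min(1, abs(sum(ax_s$direction * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 1)

  ## annotation mode reads the stored axis verbatim
  ax_a <- define_long_axis(lm, mode = "from_annotation")
  expect_equal(ax_a$direction, c(0, 0, 1), tolerance = 1e-12)

  line <- matrix(rep(1:18, 3), 18) * 2
  bad <- annulus_landmarks(line, line + 1)
  expect_error(define_long_axis(bad), class = "trimorph_degenerate_geometry")
})

test_that("generate_planes spans 360 degrees in 18 half-planes", {
  ax <- define_long_axis(phantom_landmarks(circle_phantom()))
  pl <- generate_planes(ax)
  expect_length(pl$angles_deg, 18L)
  expect_equal(diff(pl$angles_deg), rep(20, 17))
  ## opposite stations are antiparallel: one diametric image plane
  for (k in 1:9)
    expect_equal(pl$directions[k, ], -pl$directions[k + 9, ], tolerance = 1e-12)
  ## all in-plane directions are orthogonal to the axis
  expect_lt(max(abs(pl$directions %*% ax$direction)), 1e-12)
})

test_that("extract_landmarks ingests files, phantoms and landmark sets", {
  spec <- circle_phantom()
  lm <- phantom_landmarks(spec)
  expect_identical(extract_landmarks(lm), lm)

  f <- tempfile(fileext = ".json")
  write_annotation(lm, f)
  back <- read_annotation(f)
  expect_equal(back$annular, lm$annular, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$free_margin, lm$free_margin, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$traces, lm$traces, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$apm, lm$apm, tolerance = 1e-12)

  ## drop one plane -> error naming the absent angle
  doc <- jsonlite::read_json(f, simplifyVector = FALSE)
  doc$planes <- doc$planes[-4]                    # removes 60 degrees
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, digits = NA)
  err <- tryCatch(read_annotation(f2), condition = identity)
  expect_s3_class(err, "trimorph_incomplete_annotation")
  expect_match(conditionMessage(err), "60")
  unlink(c(f, f2))

  expect_error(extract_landmarks(42), class = "trimorph_invalid_parameter")
})

test_that("fit_annulus recovers phantom curves and tolerates jitter", {
  ## circle: exact representation
  fit <- fit_annulus(phantom_landmarks(circle_phantom(r = 20)))
  per <- compute_perimeters(fit)
  expect_rel_equal(per$L3D, 125.664, 1e-4)
  expect_equal(fit$centroid, c(0, 0, 0), tolerance = 1e-9)

  ## saddle built on a circle: z cos(2 theta) coefficient comes back exactly
  sad <- leaflet_spec(build_annulus("saddle", r = 20, saddle_height = 5),
                      "paraboloid", tenting_depth = 7)
  fit_s <- fit_annulus(phantom_landmarks(sad))
  expect_lt(abs(fit_s$model$a[3, 3] - 5), 1e-6)

  ## 0.5 mm isotropic landmark jitter: mean perimeter bias < 1%
  set.seed(21)
  lm0 <- phantom_landmarks(circle_phantom(r = 20))
  per_j <- replicate(100, {
    lmj <- lm0
    lmj$annular <- lm0$annular + matrix(rnorm(54, 0, 0.5), 18)
    compute_perimeters(fit_annulus(lmj))$L3D
  })
  expect_lt(abs(mean(per_j) - 125.664) / 125.664, 0.01)

  expect_error(fit_annulus(lm0, order = 9), class = "trimorph_underdetermined")
})

test_that("best_fit_plane is a total-least-squares plane", {
  set.seed(2)
  ## coplanar points: zero residual
  b <- plane_basis(unit(c(1, 2, 2)))
  pts <- outer(runif(30), b$e1) + outer(runif(30), b$e2)
  pl <- best_fit_plane(pts)
  expect_lt(max(abs(sweep(pts, 2, pl$point) %*% pl$normal)), 1e-9)

  ## saddle +-5 mm about z = 0: plane within 1e-6 of z = 0
  sad <- annulus_eval(saddle_annulus(5), seq(0, 2 * pi, length.out = 361)[-361])
  pls <- best_fit_plane(sad, orient = c(0, 0, 1))
  expect_lt(abs(pls$point[3]), 1e-6)
  expect_gt(abs(pls$normal[3]), 1 - 1e-9)
  expect_lt(sum(pls$normal * c(0, 0, 1)), 0)      # atrial orientation

  ## translation equivariance
  pl2 <- best_fit_plane(sweep(sad, 2, c(3, -2, 7), "+"), orient = c(0, 0, 1))
  expect_equal(pl2$point, pls$point + c(3, -2, 7), tolerance = 1e-9)
  expect_equal(pl2$normal, pls$normal, tolerance = 1e-9)

  expect_error(best_fit_plane(matrix(1:6, 2, 3)),
               class = "trimorph_degenerate_geometry")
  expect_error(best_fit_plane(cbind(1:9, (1:9) * 2, (1:9) * 3)),
               class = "trimorph_degenerate_geometry")
})

test_that("perimeters, areas and diameters match closed forms", {
  fit_c <- fit_annulus(phantom_landmarks(circle_phantom(r = 20)))
  per <- compute_perimeters(fit_c)
  expect_rel_equal(per$L2D, 2 * pi * 20, 1e-4)
  expect_rel_equal(per$L3D, 2 * pi * 20, 1e-4)
  ar <- compute_areas(fit_c)
  expect_rel_equal(ar$A2D, pi * 400, 1e-3)
  expect_rel_equal(ar$A3D, pi * 400, 1e-3)
  di <- compute_diameters(fit_c)
  expect_rel_equal(di$Dmax, 40, 1e-3)
  expect_rel_equal(di$Dmin, 40, 1e-3)

  ## calibration ellipse: perimeter against an independent quadrature oracle
  ell <- leaflet_spec(calib_ellipse(), "paraboloid", tenting_depth = 7)
  fit_e <- fit_annulus(phantom_landmarks(ell))
  L_oracle <- stats::integrate(function(t) sqrt(25.1^2 * sin(t)^2 +
                                                21.55^2 * cos(t)^2),
                               0, 2 * pi, rel.tol = 1e-10)$value
  expect_rel_equal(compute_perimeters(fit_e)$L2D, L_oracle, 0.005)
  expect_rel_equal(compute_areas(fit_e)$A2D, pi * 25.1 * 21.55, 0.005)
  di_e <- compute_diameters(fit_e)
  expect_rel_equal(di_e$Dmax, 50.2, 0.005)
  expect_rel_equal(di_e$Dmin, 43.1, 0.005)

  ## saddle: strict projection inequalities
  sad <- leaflet_spec(saddle_annulus(5), "paraboloid", tenting_depth = 7)
  fit_s <- fit_annulus(phantom_landmarks(sad))
  expect_gt(compute_perimeters(fit_s)$L3D, compute_perimeters(fit_s)$L2D)
  expect_gt(compute_areas(fit_s)$A3D, compute_areas(fit_s)$A2D)
})

test_that("diameters are invariant under rigid motion", {
  set.seed(31)
  ell <- leaflet_spec(calib_ellipse(), "paraboloid", tenting_depth = 7)
  lm <- phantom_landmarks(ell)
  d0 <- compute_diameters(fit_annulus(lm))
  for (rep in 1:3) {
    R <- random_rotation()
    lmr <- apply_rigid_to_landmarks(lm, R, rnorm(3, 0, 20))
    dr <- compute_diameters(fit_annulus(lmr))
    expect_rel_equal(dr$Dmax, d0$Dmax, 1e-3)
    expect_rel_equal(dr$Dmin, d0$Dmin, 1e-3)
  }
})

test_that("leaflet surface reconstruction respects its contracts", {
  ## flat leaflets: mesh within 1e-9 of the annulus plane
  flat <- leaflet_spec(build_annulus("circle", r = 20), "flat",
                       tenting_depth = 0)
  lm <- phantom_landmarks(flat)
  fit <- fit_annulus(lm)
  mesh <- reconstruct_leaflet_surface(lm, fit)
  expect_lt(max(abs(mesh$vertices[, 3])), 1e-9)
  expect_equal(tenting_volume(mesh), 0, tolerance = 1e-12)

  ## raw mode: every input point appears as a mesh vertex
  spec <- circle_phantom()
  lm2 <- phantom_landmarks(spec, n_trace = 6)
  fit2 <- fit_annulus(lm2)
  mesh2 <- reconstruct_leaflet_surface(lm2, fit2, refine = 0)
  raw_pts <- rbind(lm2$free_margin, do.call(rbind, lm2$traces),
                   matrix(lm2$apex, 1))
  dmat <- apply(raw_pts, 1, function(p)
    min(sqrt(colSums((t(mesh2$vertices) - p)^2))))
  expect_lt(max(dmat), 1e-9)

  ## refined vertices still lie on the analytic phantom surface (< 0.1 mm)
  mesh3 <- reconstruct_leaflet_surface(lm2, fit2)
  v <- mesh3$vertices
  f_v <- pmin(1, sqrt(v[, 1]^2 + v[, 2]^2) / 20)
  z_true <- 9.549 * (1 - f_v^2)
  expect_lt(max(abs(v[, 3] - z_true)), 0.1)

  expect_error(reconstruct_leaflet_surface(
    annulus_landmarks(lm2$annular, lm2$free_margin), fit2, refine = 0),
    NA)   # free-margin-only input is still >= 3 points and works
})

test_that("tenting volume scales linearly with depth on planar annuli", {
  t1 <- run_morphometry(circle_phantom(h = 4))$Tvol
  t2 <- run_morphometry(circle_phantom(h = 8))$Tvol
  expect_rel_equal(t2 / t1, 2, 0.01)
  ## strict monotonicity over a depth grid
  tv <- vapply(c(2, 4, 6, 8, 10),
               function(h) run_morphometry(circle_phantom(h = h))$Tvol, 0)
  expect_true(all(diff(tv) > 0))
})

test_that("run_morphometry composes the pipeline deterministically", {
  flat <- leaflet_spec(build_annulus("circle", r = 20), "flat",
                       tenting_depth = 0)
  m <- run_morphometry(flat)
  expect_rel_equal(m$L2D, 125.664, 1e-3)
  expect_rel_equal(m$L3D, 125.664, 1e-3)
  expect_rel_equal(m$A2D, 1256.64, 1e-3)
  expect_rel_equal(m$A3D, 1256.64, 1e-3)
  expect_rel_equal(m$Dmax, 40, 1e-3)
  expect_rel_equal(m$Dmin, 40, 1e-3)
  expect_lt(abs(m$Tvol), 1e-9)
  expect_true(m$L3D >= m$L2D && m$A3D >= m$A2D && m$Dmax >= m$Dmin)

  m2 <- run_morphometry(flat)
  expect_identical(unclass(m)[1:7], unclass(m2)[1:7])
  expect_identical(m$provenance$input_hash, m2$provenance$input_hash)
})

test_that("all seven metrics are rigid-motion invariant to 0.1%", {
  set.seed(77)
  spec <- leaflet_spec(saddle_annulus(4), "paraboloid", tenting_depth = 7)
  lm <- phantom_landmarks(spec)
  base <- run_morphometry(lm)
  keys <- c("L2D", "L3D", "A2D", "A3D", "Dmax", "Dmin", "Tvol")
  for (rep in 1:2) {
    R <- random_rotation()
    rot <- run_morphometry(apply_rigid_to_landmarks(lm, R, rnorm(3, 0, 30)))
    for (k in keys) expect_rel_equal(rot[[k]], base[[k]], 0.001)
  }
})
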