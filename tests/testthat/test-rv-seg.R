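test_that("crop_roi keeps world coordinates intact", {
  vol <- voxel_volume(array(seq_len(20^3), c(20, 20, 20)), spacing = 1,
                      origin = c(-10, -10, -10))
  full <- crop_roi(vol, c(-10, -10, -10), c(9, 9, 9))
  expect_identical(full$data, vol$data)

  half <- crop_roi(vol, c(-10, -10, -10), c(-0.6, 9, 9))
  expect_lte(abs(dim(half$data)[1] - 10), 1)

  ## a voxel inside the ROI keeps its world position
  idx_w <- trimorph:::index_to_world(vol, c(5, 6, 7))
  sub <- crop_roi(vol, c(-8, -8, -8), c(5, 5, 5))
  val <- vol$data[5, 6, 7]
  pos <- which(sub$data == val, arr.ind = TRUE)
  expect_equal(trimorph:::index_to_world(sub, as.numeric(pos)),
               idx_w, tolerance = 1e-12)

  expect_error(crop_roi(vol, c(50, 50, 50), c(60, 60, 60)),
               class = "trimorph_bounds_error")
})

test_that("compute_speed_image maps thresholds to [-1, 1]", {
  arr <- array(0, c(3, 3, 3))
  arr[] <- seq(0, 260, length.out = 27)
  vol <- voxel_volume(arr, spacing = 1)

  hard <- compute_speed_image(vol, threshold_spec(100, 200))
  expect_true(all(hard$data %in% c(-1, 1)))
  expect_true(all(hard$data[arr >= 100 & arr <= 200] == 1))
  expect_true(all(hard$data[arr < 100 | arr > 200] == -1))

  soft <- compute_speed_image(vol, threshold_spec(100, 200, ramp_width = 10))
  mid_val <- array(95, c(2, 2, 2))                 # lower - 5 on a ramp of 10
  s <- compute_speed_image(voxel_volume(mid_val, 1), threshold_spec(100, 200, 10))
  expect_equal(unique(as.numeric(s$data)), 0)
  inside <- array(150, c(2, 2, 2))
  s2 <- compute_speed_image(voxel_volume(inside, 1), threshold_spec(100, 200, 10))
  expect_equal(unique(as.numeric(s2$data)), 1)
  expect_true(all(soft$data >= -1 & soft$data <= 1))

  expect_error(threshold_spec(10, 5), class = "trimorph_invalid_parameter")
})

test_that("region_grow equals thresholded connected components on binary speed", {
  ## sphere of positive speed in negative background
  d <- c(21, 21, 21)
  co <- lapply(d, function(n) seq_len(n) - 11)
  rsq <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  arr <- ifelse(rsq <= 7^2, 150, 0)
  vol <- voxel_volume(arr, spacing = 1, origin = c(-10, -10, -10))
  speed <- compute_speed_image(vol, threshold_spec(100, 200))
  mask <- region_grow(speed, c(11, 11, 11))
  oracle <- cc_oracle(speed$data > 0, c(11, 11, 11))
  expect_identical(mask$data, oracle)
  expect_false(mask$capped)

  ## uniform positive speed floods the grid
  all_pos <- compute_speed_image(voxel_volume(array(150, c(5, 5, 5)), 1),
                                 threshold_spec(100, 200))
  expect_true(all(region_grow(all_pos, c(3, 3, 3))$data))

  ## two disjoint blobs: only the seeded one grows
  arr2 <- array(0, c(20, 10, 10))
  arr2[2:5, 3:6, 3:6] <- 150
  arr2[14:17, 3:6, 3:6] <- 150
  sp2 <- compute_speed_image(voxel_volume(arr2, 1), threshold_spec(100, 200))
  m2 <- region_grow(sp2, c(3, 4, 4))
  expect_true(all(m2$data[2:5, 3:6, 3:6]))
  expect_false(any(m2$data[14:17, , ]))

  ## max_iter caps the front and is flagged
  capped <- region_grow(all_pos, c(3, 3, 3), max_iter = 1)
  expect_true(capped$capped)
  expect_lt(sum(capped$data), 125)

  err <- tryCatch(region_grow(sp2, c(10, 5, 5)), condition = identity)
  expect_s3_class(err, "trimorph_bad_seed")
  expect_match(conditionMessage(err), "seed 1")
})

test_that("refine_mask applies ordered set edits", {
  base <- array(FALSE, c(20, 20, 20))
  base[5:15, 5:15, 5:15] <- TRUE
  mask <- structure(list(data = base, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), capped = FALSE),
                    class = "segmentation_mask")
  expect_identical(refine_mask(mask, list())$data, base)

  rm_sphere <- list(list(op = "remove", shape = "sphere",
                         center = c(10, 10, 10), radius = 3))
  cut <- refine_mask(mask, rm_sphere)
  expect_false(cut$data[10, 10, 10])
  expect_true(sum(cut$data) < sum(base))

  ## add then remove the same sphere: final state excludes it entirely
  both <- refine_mask(mask, list(
    list(op = "add", shape = "sphere", center = c(3, 3, 3), radius = 2),
    list(op = "remove", shape = "sphere", center = c(3, 3, 3), radius = 2)))
  expect_false(any(both$data[1:5, 1:5, 1:5]))

  bx <- refine_mask(mask, list(list(op = "add", shape = "box",
                                    min = c(0, 0, 0), max = c(2, 2, 2))))
  expect_true(all(bx$data[1:3, 1:3, 1:3]))

  expect_error(refine_mask(mask, list(list(op = "remove", shape = "sphere",
                                           center = c(100, 100, 100),
                                           radius = 2))),
               class = "trimorph_bounds_error")
})

test_that("quantify_volume counts voxels times voxel volume", {
  empty <- structure(list(data = array(FALSE, c(4, 4, 4)),
                          spacing = c(0.5, 0.5, 0.5), origin = c(0, 0, 0),
                          capped = FALSE), class = "segmentation_mask")
  expect_equal(quantify_volume(empty), 0)
  full <- empty
  full$data <- array(TRUE, c(20, 20, 20))          # 8000 voxels at 0.5 mm
  expect_equal(quantify_volume(full), 1.0)
})

test_that("segmented volume is monotone in the upper threshold", {
  set.seed(4)
  arr <- array(runif(30^3, 0, 255), c(30, 30, 30))
  arr[13:17, 13:17, 13:17] <- 120                  # guaranteed seed region
  vol <- voxel_volume(arr, spacing = 1)
  vols <- vapply(c(140, 180, 220, 255), function(up) {
    segment_rv(vol, threshold_spec(100, up),
               seeds = matrix(c(14, 14, 14), 1))$volume_ml
  }, 0)
  expect_true(all(diff(vols) >= 0))
})

test_that("ellipsoid volumetry is accurate at 0.5 mm", {
  spec <- rv_phantom_spec(c(25, 22, 20))
  rv <- build_rv_phantom(spec, spacing = 0.5)
  seg <- segment_rv(rv$volume, default_rv_thresholds(spec),
                    seeds = matrix(c(0, 0, 0), 1))
  expect_rel_equal(seg$volume_ml, rv$true_volume, 0.01)
})
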