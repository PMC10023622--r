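test_that("check_normality enforces its range and flags degeneracy", {
  expect_error(check_normality(c(1, 2)), class = "trimorph_invalid_parameter")
  expect_error(check_normality(rnorm(51)), class = "trimorph_invalid_parameter")
  expect_error(check_normality(rep(3, 10)), class = "trimorph_degenerate_data")
  res <- check_normality(seq(1, 10))
  expect_gt(res$W, 0.95)
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("paired_t_test matches the hand-computed example exactly", {
  pm <- paired_measurements("x", c(1, 2, 3, 4), c(2, 2, 4, 5))
  tt <- paired_t_test(pm)
  ## d = (1, 0, 1, 1): mean 0.75, sd 0.5, t = 0.75 / (0.5 / 2) = 3
  expect_equal(tt$t, 3, tolerance = 1e-12)
  expect_identical(tt$df, 3)
  expect_equal(tt$p, 2 * pt(-3, 3), tolerance = 1e-12)
  expect_equal(tt$p, 0.05766889, tolerance = 1e-6)

  ## antisymmetry
  rev <- paired_t_test(paired_measurements("x", c(2, 2, 4, 5), c(1, 2, 3, 4)))
  expect_equal(rev$t, -tt$t, tolerance = 1e-12)
  expect_equal(rev$p, tt$p, tolerance = 1e-12)

  ## dual route: agrees with the reference implementation on random pairs
  set.seed(8)
  for (rep in 1:5) {
    f <- rnorm(10, 10, 2); d <- f + rnorm(10, 0.5, 1)
    ours <- paired_t_test(paired_measurements("m", f, d))
    ref <- t.test(d, f, paired = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  expect_error(paired_t_test(paired_measurements("x", c(1, 2, 3), c(2, 3, 4))),
               class = "trimorph_degenerate_data")
  expect_error(paired_measurements("x", 1:3, 1:4),
               class = "trimorph_invalid_parameter")
  expect_error(paired_measurements("x", c(1, NA, 3), c(1, 2, 3)),
               class = "trimorph_invalid_parameter")
})

test_that("mean_variation averages per-sample percent changes", {
  expect_equal(mean_variation(paired_measurements("x", c(3, 7), c(3, 7))), 0)
  expect_equal(mean_variation(paired_measurements("x", c(1, 2), c(2, 3))), 75)

  ## scale invariance: (fresh, fresh (1 + c)) -> 100 c for any scaling
  set.seed(9)
  f <- runif(10, 1, 5)
  for (c_ in c(-0.5, 0.1, 2)) {
    pm <- paired_measurements("x", f, f * (1 + c_))
    expect_equal(mean_variation(pm), 100 * c_, tolerance = 1e-9)
    pm_scaled <- paired_measurements("x", 7.3 * f, 7.3 * f * (1 + c_))
    expect_equal(mean_variation(pm_scaled), 100 * c_, tolerance = 1e-9)
  }

  expect_error(mean_variation(paired_measurements("x", c(0, 1), c(1, 2))),
               class = "trimorph_degenerate_data")
})

test_that("build_summary renders one deterministic row per metric", {
  pm1 <- paired_measurements("A", c(5, 5, 5), c(6, 6.5, 6.2), unit = "mm")
  pm0 <- paired_measurements("B", c(2, 2, 2), c(3, 3, 3), unit = "mL")
  s <- build_summary(list(pm1, pm0))
  expect_identical(s$metric, c("A", "B"))
  expect_equal(s$fresh_sd[1], 0)
  expect_true(is.na(s$p_value[2]))                # zero-variance differences
  expect_equal(s$mean_variation_pct[2], 50)

  md <- format_summary_md(s)
  expect_match(md[3], "^\\| A \\(mm\\)")

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(s, f1, row.names = FALSE)
  write.csv(build_summary(list(pm1, pm0)), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))

  expect_error(build_summary(list()), class = "trimorph_invalid_parameter")
})

test_that("summary of a synthetic cohort tracks configured targets", {
  coh <- sample_cohort(cohort_config(n_samples = 10, seed = 5))
  t1 <- table1_targets()
  pms <- lapply(unique(coh$metric), function(m) {
    sub <- coh[coh$metric == m, ]
    paired_measurements(m, sub$fresh, sub$defrosted)
  })
  s <- build_summary(pms)
  idx <- match(s$metric, t1$metric)
  tol <- 4 * t1$fresh_sd[idx] / sqrt(10)
  expect_true(all(abs(s$fresh_mean - t1$fresh_mean[idx]) <= tol))
})

test_that("long-format measurement CSVs round-trip", {
  df <- data.frame(metric = rep(c("TRF", "CO"), each = 6),
                   sample_id = rep(1:3, 4),
                   condition = rep(rep(c("fresh", "defrosted"), each = 3), 2),
                   value = rnorm(12, 10))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  pms <- read_measurements(f)
  expect_length(pms, 2L)
  expect_identical(pms[[1]]$metric, "TRF")
  expect_equal(pms[[1]]$fresh,
               df$value[df$metric == "TRF" & df$condition == "fresh"],
               tolerance = 1e-12)
  unlink(f)
})
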