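test_that("make_pump_flow ejects the stroke volume over the systolic window", {
  st <- pump_settings()
  pf <- make_pump_flow(st, 1)
  expect_length(pf$q, 200L)                       # fs * 60 / HR
  expect_rel_equal(sum(pf$q) / 200, 70, 0.001)    # per-cycle volume, 0.1%
  expect_true(all(pf$q[pf$t >= 0.35] == 0))

  z <- make_pump_flow(pump_settings(stroke_volume = 0), 3)
  expect_true(all(z$q == 0))

  pf3 <- make_pump_flow(st, 3)
  expect_length(pf3$q, 600L)
  expect_equal(pf3$q[1:200], pf3$q[201:400])

  expect_error(pump_settings(systolic_fraction = 1.2),
               class = "trimorph_invalid_parameter")
  expect_error(make_pump_flow(st, 0), class = "trimorph_invalid_parameter")
})

test_that("split_flows shapes the regurgitant lobes and conserves volume", {
  st <- pump_settings()
  clean <- split_flows(st, 0, 0, n_cycles = 2)
  expect_true(all(clean$q_tv >= 0))
  expect_true(all(clean$q_pulm >= 0))

  wf <- split_flows(st, 50, 0, n_cycles = 1)
  neg_vol <- sum(pmax(-wf$q_tv, 0)) / st$fs       # trapezoid (periodic)
  expect_rel_equal(neg_vol, 35, 0.005)

  ## per-cycle balance: forward TV - TV backflow = forward pulm - PRV
  for (trf in c(0, 25, 50, 67.1, 84)) for (prv in c(0, 4, 8)) {
    w <- split_flows(st, trf, prv, n_cycles = 1)
    lhs <- sum(pmax(w$q_tv, 0)) / st$fs - sum(pmax(-w$q_tv, 0)) / st$fs
    rhs <- sum(pmax(w$q_pulm, 0)) / st$fs - sum(pmax(-w$q_pulm, 0)) / st$fs
    expect_lt(abs(lhs - rhs) / 70, 0.005)
  }

  expect_error(split_flows(st, 100, 0), class = "trimorph_invalid_parameter")
  expect_error(split_flows(st, 10, -1), class = "trimorph_invalid_parameter")
})

test_that("windkessel integrator matches closed forms", {
  wk <- windkessel_params(Rp = 1.0)
  expect_equal(wk$Rc, 0.029)
  expect_equal(wk$C, 16.5)

  expect_true(all(simulate_windkessel(wk, rep(0, 100), dt = 1 / 200, p0 = 0) == 0))

  ## constant inflow from the periodic start sits at q (Rc + Rp) immediately
  pap <- simulate_windkessel(wk, rep(20, 1000), dt = 1 / 200)
  expect_rel_equal(mean(pap), 20 * (0.029 + 1.0), 1e-6)

  ## free decay has time constant Rp C = 16.5 s
  dec <- simulate_windkessel(wk, rep(0, 2001), dt = 1 / 200, p0 = 10)
  expect_rel_equal(dec[2001], 10 * exp(-10 / 16.5), 1e-9)

  ## cycle-to-cycle mean drift < 0.5% after >= 5 cycles
  st <- pump_settings()
  wf <- split_flows(st, 67.1, 7.9, n_cycles = 10)
  p <- simulate_windkessel(wk, wf$q_pulm, dt = 1 / st$fs, cycle_samples = 200)
  cm <- colMeans(matrix(p, nrow = 200))
  drift <- abs(diff(cm[5:10])) / cm[5:9]
  expect_true(all(drift < 0.005))

  expect_error(windkessel_params(Rp = 0), class = "trimorph_invalid_parameter")
})

test_that("steady orifice model follows the square-root law", {
  expect_equal(steady_backflow(orifice_model(eroa = 0), 20), 0)

  om <- orifice_model(eroa = 25)
  expect_rel_equal(steady_backflow(om, 30) / steady_backflow(om, 15),
                   sqrt(2), 1e-12)

  cal <- calibrate_orifice(0.4, 15)
  expect_rel_equal(steady_backflow(cal, 15), 0.4, 1e-12)
  expect_rel_equal(steady_backflow(cal, 30), 0.4 * sqrt(2), 1e-12)

  ## monotone in both pressure and orifice area
  q <- steady_backflow(om, c(0, 5, 15, 30))
  expect_true(all(diff(q) > 0) && q[1] == 0)
  expect_gt(steady_backflow(orifice_model(eroa = 30), 15),
            steady_backflow(orifice_model(eroa = 25), 15))

  expect_error(steady_backflow(om, -1), class = "trimorph_invalid_parameter")
  expect_error(orifice_model(eroa = 10, cd = 1.5),
               class = "trimorph_invalid_parameter")
})

test_that("add_noise hits the requested SNR and is seed-deterministic", {
  st <- pump_settings()
  wf <- split_flows(st, 50, 5, n_cycles = 10)
  expect_identical(add_noise(wf, Inf), wf)
  n1 <- add_noise(wf, 20, seed = 4)
  n2 <- add_noise(wf, 20, seed = 4)
  expect_identical(n1, n2)
  expect_false(identical(n1$q_tv, add_noise(wf, 20, seed = 5)$q_tv))

  ## empirical SNR within 1 dB
  noise <- n1$q_pulm - wf$q_pulm
  snr_emp <- 10 * log10(mean((wf$q_pulm - mean(wf$q_pulm))^2) / mean(noise^2))
  expect_lt(abs(snr_emp - 20), 1)
})

test_that("waveform CSV round-trips", {
  st <- pump_settings()
  wf <- split_flows(st, 30, 3, n_cycles = 2)
  wf$pap <- simulate_windkessel(windkessel_params(), wf$q_pulm, dt = 1 / st$fs,
                                cycle_samples = 200)
  f <- tempfile(fileext = ".csv")
  write_waveforms(wf, f)
  back <- read_waveforms(f)
  expect_equal(back$q_tv, wf$q_tv, tolerance = 1e-10)
  expect_equal(back$q_pulm, wf$q_pulm, tolerance = 1e-10)
  expect_equal(back$pap, wf$pap, tolerance = 1e-10)
  expect_equal(back$fs, 200)
  unlink(f)
})
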