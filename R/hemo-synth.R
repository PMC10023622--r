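## Pulsatile waveform synthesis and lumped-parameter hemodynamics.
##
## The pulsatile rig pushes saline from a positive-displacement pump through
## the right ventricle and pulmonary valve into a three-element Windkessel
## pulmonary impedance simulator; flows are sampled at 200 Hz over 10 paced
## cycles. The waveform generator reproduces that stated world: half-sine
## systolic ejection, a systolic tricuspid backflow lobe sized to the target
## regurgitant fraction, an early-diastolic pulmonary leak sized to the
## target regurgitant volume, and a diastolic filling lobe closing the
## per-cycle volume balance.

#' Three-element Windkessel parameters
#'
#' Characteristic resistance in series with a parallel compliance and
#' peripheral resistance (pulmonary input impedance of the rig).
#'
#' @param Rc characteristic resistance, mmHg s/mL.
#' @param C compliance, mL/mmHg.
#' @param Rp peripheral resistance, mmHg s/mL (rig-adjustable 0.22-1.18).
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(Rc = 0.029, C = 16.5, Rp = 1.0) {
  for (nm in c("Rc", "C", "Rp"))
    assert_scalar_num(get(nm), nm, positive = TRUE)
  structure(list(Rc = Rc, C = C, Rp = Rp), class = "windkessel_params")
}

#' Pulsatile pump settings
#'
#' @param heart_rate paced rate, bpm.
#' @param stroke_volume pump stroke volume, mL.
#' @param systolic_fraction ejection fraction of the cycle duration.
#' @param fs sampling frequency, Hz.
#' @return An object of class `pump_settings`.
#' @export
pump_settings <- function(heart_rate = 60, stroke_volume = 70,
                          systolic_fraction = 0.35, fs = 200) {
  assert_scalar_num(heart_rate, "heart_rate", positive = TRUE)
  assert_scalar_num(stroke_volume, "stroke_volume", nonneg = TRUE)
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop_trimorph("systolic_fraction must be in (0, 1)", "trimorph_invalid_parameter")
  structure(list(heart_rate = heart_rate, stroke_volume = stroke_volume,
                 systolic_fraction = systolic_fraction, fs = fs),
            class = "pump_settings")
}

samples_per_cycle <- function(settings)
  as.integer(round(settings$fs * 60 / settings$heart_rate))

## half-sine lobe of prescribed volume over [t0, t1), evaluated at times t
lobe <- function(t, t0, t1, volume) {
  w <- t1 - t0
  amp <- volume * pi / (2 * w)
  inside <- t >= t0 & t < t1
  out <- numeric(length(t))
  out[inside] <- amp * sin(pi * (t[inside] - t0) / w)
  out
}

#' Pump outflow waveform
#'
#' Half-sinusoid ejection over the systolic fraction of each cycle; the
#' per-cycle ejected volume equals the stroke volume.
#'
#' @param settings a [pump_settings()].
#' @param n_cycles number of cycles, >= 1.
#' @return list with `t` (s) and `q` (mL/s), sampled at `fs`.
#' @export
make_pump_flow <- function(settings = pump_settings(), n_cycles = 10L) {
  stopifnot(inherits(settings, "pump_settings"))
  if (n_cycles < 1) stop_trimorph("n_cycles must be >= 1", "trimorph_invalid_parameter")
  period <- 60 / settings$heart_rate
  n <- samples_per_cycle(settings) * as.integer(n_cycles)
  t <- (seq_len(n) - 1L) / settings$fs
  tc <- t %% period
  q <- lobe(tc, 0, settings$systolic_fraction * period, settings$stroke_volume)
  list(t = t, q = q)
}

#' Split pump flow into pulmonary and tricuspid branches
#'
#' Builds the two valve flows implied by target regurgitation indexes. Per
#' cycle: the tricuspid flow carries a systolic backflow lobe of volume
#' `trf_target/100 * SV` and a diastolic filling lobe of volume `SV - PRV`;
#' the pulmonary flow carries the complementary forward volume `SV * (1 -
#' trf_target/100)` in systole and an early-diastolic regurgitant lobe of
#' volume `prv_target`. The per-cycle balance "forward tricuspid - tricuspid
#' backflow = forward pulmonary - PRV" holds by construction.
#'
#' @param settings a [pump_settings()].
#' @param trf_target tricuspid regurgitant fraction, percent, in `[0, 100)`.
#' @param prv_target pulmonary regurgitant volume, mL/cycle, >= 0.
#' @param n_cycles number of cycles.
#' @return An object of class `flow_waveform_set`: list with `t`, `q_pulm`,
#'   `q_tv` (mL/s), `pap` (`NULL` until [simulate_windkessel()] fills it),
#'   `fs`, `heart_rate`, `n_cycles`, `stroke_volume`.
#' @export
split_flows <- function(settings = pump_settings(), trf_target = 0,
                        prv_target = 0, n_cycles = 10L) {
  stopifnot(inherits(settings, "pump_settings"))
  if (trf_target < 0 || trf_target >= 100)
    stop_trimorph("trf_target must be in [0, 100) percent", "trimorph_invalid_parameter")
  assert_scalar_num(prv_target, "prv_target", nonneg = TRUE)
  period <- 60 / settings$heart_rate
  sv <- settings$stroke_volume
  v_reg <- trf_target / 100 * sv
  pf <- make_pump_flow(settings, n_cycles)
  tc <- pf$t %% period
  ts <- settings$systolic_fraction * period
  q_pulm <- lobe(tc, 0, ts, sv - v_reg) -
    lobe(tc, ts, ts + 0.15 * period, prv_target)
  q_tv <- -lobe(tc, 0, ts, v_reg) +
    lobe(tc, ts + 0.15 * period, period, sv - prv_target)
  structure(list(t = pf$t, q_pulm = q_pulm, q_tv = q_tv, pap = NULL,
                 fs = settings$fs, heart_rate = settings$heart_rate,
                 n_cycles = as.integer(n_cycles), stroke_volume = sv),
            class = "flow_waveform_set")
}

#' @export
print.flow_waveform_set <- function(x, ...) {
  cat(sprintf("<flow_waveform_set> %d cycles at %g bpm, fs %g Hz%s\n",
              x$n_cycles, x$heart_rate, x$fs,
              if (is.null(x$pap)) "" else ", with PAP"))
  invisible(x)
}

#' Simulate pulmonary artery pressure with a three-element Windkessel
#'
#' Integrates `C dPc/dt = q - Pc/Rp` with `pap = Rc q + Pc` by fixed-step
#' 4th-order Runge-Kutta at the sampling interval (flow linearly
#' interpolated at half-steps). By default the compliance state starts on
#' the periodic orbit (computed in closed form from one cycle of flow), so
#' there is no start-up transient; pass `p0` to start elsewhere.
#'
#' @param params a [windkessel_params()].
#' @param q pulmonary flow, mL/s, uniformly sampled.
#' @param dt sampling interval, s.
#' @param p0 initial compliance pressure, mmHg, or `NULL` for the periodic
#'   steady state (requires `cycle_samples`).
#' @param cycle_samples samples per cycle (used for the periodic start).
#' @param substeps RK4 substeps per sample (for convergence studies).
#' @return pap, mmHg, same length as `q`.
#' @export
simulate_windkessel <- function(params, q, dt, p0 = NULL,
                                cycle_samples = NULL, substeps = 1L) {
  stopifnot(inherits(params, "windkessel_params"))
  assert_scalar_num(dt, "dt", positive = TRUE)
  tau <- params$Rp * params$C
  if (is.null(p0)) {
    ncs <- cycle_samples %||% length(q)
    qc <- q[seq_len(min(ncs, length(q)))]
    Tcyc <- length(qc) * dt
    ## periodic solution of the linear ODE:
    ## Pc(0) = ( int_0^T e^{-(T-s)/tau} q(s)/C ds ) / (1 - e^{-T/tau})
    s <- (seq_along(qc) - 0.5) * dt
    p0 <- sum(exp(-(Tcyc - s) / tau) * qc) * dt / params$C /
      (1 - exp(-Tcyc / tau))
  }
  pc <- windkessel_rk4(q, dt, params$Rp, params$C, p0, as.integer(substeps))
  params$Rc * q + pc
}

## RK4 in R; flow between samples by linear interpolation.
windkessel_rk4 <- function(q, dt, Rp, C, p0, substeps = 1L) {
  n <- length(q)
  pc <- numeric(n)
  pc[1L] <- p0
  h <- dt / substeps
  f <- function(qq, p) (qq - p / Rp) / C
  for (i in seq_len(n - 1L)) {
    p <- pc[i]
    for (s in seq_len(substeps)) {
      a0 <- (s - 1) / substeps; a1 <- s / substeps
      q0 <- q[i] + a0 * (q[i + 1L] - q[i])
      qh <- q[i] + (a0 + a1) / 2 * (q[i + 1L] - q[i])
      q1 <- q[i] + a1 * (q[i + 1L] - q[i])
      k1 <- f(q0, p)
      k2 <- f(qh, p + h / 2 * k1)
      k3 <- f(qh, p + h / 2 * k2)
      k4 <- f(q1, p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    pc[i + 1L] <- p
  }
  pc
}

#' Steady orifice (Bernoulli) regurgitant flow model
#'
#' @param eroa effective regurgitant orifice area, mm^2.
#' @param cd discharge coefficient in (0, 1].
#' @param rho fluid density, kg/m^3 (saline by default).
#' @return An object of class `orifice_model`.
#' @export
orifice_model <- function(eroa, cd = 0.7, rho = 1000) {
  assert_scalar_num(eroa, "eroa", nonneg = TRUE)
  assert_scalar_num(rho, "rho", positive = TRUE)
  if (cd <= 0 || cd > 1)
    stop_trimorph("cd must be in (0, 1]", "trimorph_invalid_parameter")
  structure(list(eroa = eroa, cd = cd, rho = rho), class = "orifice_model")
}

MMHG_TO_PA <- 133.322387415

#' Steady backflow through a closed-valve orifice
#'
#' `Q = cd * EROA * sqrt(2 dP / rho)`, returned in L/min.
#'
#' @param model an [orifice_model()].
#' @param delta_p transvalvular pressure, mmHg, >= 0.
#' @return flow, L/min.
#' @export
steady_backflow <- function(model, delta_p) {
  stopifnot(inherits(model, "orifice_model"))
  if (any(delta_p < 0))
    stop_trimorph("delta_p must be >= 0", "trimorph_invalid_parameter")
  v <- model$cd * sqrt(2 * delta_p * MMHG_TO_PA / model$rho)   # m/s
  model$eroa * 1e-6 * v * 60000                                # L/min
}

#' Calibrate an orifice area to a measured steady backflow
#'
#' @param q_lmin target flow, L/min, at pressure `delta_p`.
#' @param delta_p calibration pressure, mmHg, > 0.
#' @inheritParams orifice_model
#' @return An [orifice_model()] with the implied EROA.
#' @export
calibrate_orifice <- function(q_lmin, delta_p, cd = 0.7, rho = 1000) {
  assert_scalar_num(q_lmin, "q_lmin", nonneg = TRUE)
  assert_scalar_num(delta_p, "delta_p", positive = TRUE)
  v <- cd * sqrt(2 * delta_p * MMHG_TO_PA / rho)
  orifice_model(eroa = q_lmin / 60000 / v * 1e6, cd = cd, rho = rho)
}

#' Add channel-wise Gaussian noise to a waveform set
#'
#' @param wf a `flow_waveform_set`.
#' @param snr_db target signal-to-noise ratio per channel, dB; `Inf` returns
#'   the input unchanged.
#' @param seed RNG seed (deterministic output).
#' @return A `flow_waveform_set` with noisy channels.
#' @export
add_noise <- function(wf, snr_db, seed = 1L) {
  stopifnot(inherits(wf, "flow_waveform_set"))
  if (is.infinite(snr_db) && snr_db > 0) return(wf)
  assert_scalar_num(snr_db, "snr_db")
  noisy <- function(x, key) {
    if (is.null(x)) return(NULL)
    p_sig <- mean((x - mean(x))^2)
    sd_n <- sqrt(p_sig / 10^(snr_db / 10))
    x + with_seed(seed + key, rnorm(length(x), 0, sd_n))
  }
  wf$q_pulm <- noisy(wf$q_pulm, 1L)
  wf$q_tv <- noisy(wf$q_tv, 2L)
  wf$pap <- noisy(wf$pap, 3L)
  wf
}

#' Write / read a waveform set as CSV
#'
#' Columns `t_s, pap_mmHg, q_pulm_mls, q_tv_mls`, one header line.
#'
#' @param wf a `flow_waveform_set`.
#' @param path output path.
#' @return `path` (write) or a `flow_waveform_set` (read).
#' @export
write_waveforms <- function(wf, path) {
  stopifnot(inherits(wf, "flow_waveform_set"))
  df <- data.frame(t_s = wf$t,
                   pap_mmHg = wf$pap %||% rep(NA_real_, length(wf$t)),
                   q_pulm_mls = wf$q_pulm, q_tv_mls = wf$q_tv)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveforms
#' @param heart_rate,stroke_volume acquisition metadata not stored in the
#'   CSV, supplied on read.
#' @export
read_waveforms <- function(path, heart_rate = 60, stroke_volume = 70) {
  df <- read.csv(path)
  need <- c("t_s", "pap_mmHg", "q_pulm_mls", "q_tv_mls")
  if (!all(need %in% names(df)))
    stop_trimorph("waveform CSV must have columns t_s, pap_mmHg, q_pulm_mls, q_tv_mls",
                  "trimorph_io_error")
  dt <- diff(df$t_s)
  if (length(dt) < 1L || max(abs(dt - dt[1L])) > 1e-9)
    stop_trimorph("waveform time base must be uniform", "trimorph_io_error")
  fs <- 1 / dt[1L]
  pap <- if (all(is.na(df$pap_mmHg))) NULL else df$pap_mmHg
  structure(list(t = df$t_s, q_pulm = df$q_pulm_mls, q_tv = df$q_tv_mls,
                 pap = pap, fs = fs, heart_rate = heart_rate,
                 n_cycles = as.integer(floor(nrow(df) / (fs * 60 / heart_rate))),
                 stroke_volume = stroke_volume),
            class = "flow_waveform_set")
}
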