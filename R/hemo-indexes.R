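## Hemodynamic indexes computed from waveform records.
##
## The rig is paced, so cycles are segmented at the nominal fixed period
## 60/HR from record start (no peak detection). Per-cycle integrals use the
## periodic trapezoidal rule (sum * dt, the trapezoid with wrap-around
## closure), exact for band-limited periodic signals; non-periodic records
## (steady backflow) use the plain trapezoid.

#' Ensemble-average a waveform record over cardiac cycles
#'
#' @param wf a `flow_waveform_set` (see [split_flows()] / [read_waveforms()]).
#' @param heart_rate paced rate, bpm (defaults to the record's).
#' @param n_cycles cycles to average (default 10); the record must contain at
#'   least that many full cycles, any trailing partial cycle is discarded.
#' @return An object of class `averaged_cycle`: list with `t` (one period),
#'   `q_pulm`, `q_tv`, `pap` (possibly `NULL`), `fs`, `n_cycles_used`.
#' @export
ensemble_average <- function(wf, heart_rate = NULL, n_cycles = 10L) {
  stopifnot(inherits(wf, "flow_waveform_set"))
  heart_rate <- heart_rate %||% wf$heart_rate
  n_per <- as.integer(round(wf$fs * 60 / heart_rate))
  avail <- floor(length(wf$t) / n_per)
  if (avail < n_cycles)
    stop_trimorph(sprintf("record holds %d full cycles, %d requested",
                          avail, n_cycles),
                  "trimorph_insufficient_cycles", available = avail)
  fold <- function(x) {
    if (is.null(x)) return(NULL)
    rowMeans(matrix(x[seq_len(n_per * n_cycles)], nrow = n_per))
  }
  structure(list(t = (seq_len(n_per) - 1L) / wf$fs,
                 q_pulm = fold(wf$q_pulm), q_tv = fold(wf$q_tv),
                 pap = fold(wf$pap), fs = wf$fs,
                 n_cycles_used = as.integer(n_cycles)),
            class = "averaged_cycle")
}

#' Tricuspid regurgitant fraction
#'
#' Ratio of the tricuspid backflow volume (time integral of the negative
#' tricuspid flow over one cycle) to the ventricular systolic stroke volume,
#' as a percentage.
#'
#' @param cycle an `averaged_cycle`.
#' @param stroke_volume pump stroke volume, mL, > 0.
#' @return TRF, percent.
#' @export
compute_trf <- function(cycle, stroke_volume = 70) {
  stopifnot(inherits(cycle, "averaged_cycle"))
  assert_scalar_num(stroke_volume, "stroke_volume", positive = TRUE)
  backflow <- trapz_periodic(pmax(-cycle$q_tv, 0), 1 / cycle$fs)
  100 * backflow / stroke_volume
}

#' Cardiac output
#'
#' Mean pulmonary flow over the cycle, converted to L/min.
#'
#' @param cycle an `averaged_cycle`.
#' @return CO, L/min.
#' @export
compute_co <- function(cycle) {
  stopifnot(inherits(cycle, "averaged_cycle"))
  mean(cycle$q_pulm) * 0.06
}

#' Pulmonary regurgitant volume
#'
#' Per-cycle time integral of the negative (retrograde) pulmonary flow.
#' Two estimators of the same quantity:
#' * `"lobe"` (default): integrates `-q` over the contiguous run of
#'   negative samples containing the flow minimum — the retrograde lobe.
#'   Identical to `"rectified"` on clean signals, but free of the
#'   noise-rectification bias (`E[max(0, N)] > 0`) that inflates the
#'   rectified integral over the long zero-flow portion of the cycle.
#' * `"rectified"`: `integral of max(-q, 0)` over the whole cycle.
#'
#' @param cycle an `averaged_cycle`.
#' @param method `"lobe"` or `"rectified"`.
#' @return PRV, mL.
#' @export
compute_prv <- function(cycle, method = c("lobe", "rectified")) {
  stopifnot(inherits(cycle, "averaged_cycle"))
  method <- match.arg(method)
  q <- cycle$q_pulm
  dt <- 1 / cycle$fs
  if (method == "rectified" || all(q >= 0))
    return(trapz_periodic(pmax(-q, 0), dt))
  n <- length(q)
  i_min <- which.min(q)
  neg <- q < 0
  ## walk the contiguous negative run containing the minimum (periodic)
  lo <- i_min
  while (neg[(lo - 2L) %% n + 1L] && lo != i_min + 1L) lo <- (lo - 2L) %% n + 1L
  hi <- i_min
  while (neg[hi %% n + 1L] && hi %% n + 1L != lo) hi <- hi %% n + 1L
  idx <- if (lo <= hi) lo:hi else c(lo:n, 1L:hi)
  sum(-q[idx]) * dt
}

#' Steady-flow backflow readout
#'
#' Mean of the trailing fraction of a steady-flow record, with a
#' steady-state check: if the linear trend over the trailing half exceeds
#' 1 %/s of the mean, the reading is flagged as unsettled.
#'
#' @param flow flow record, L/min.
#' @param dt sampling interval, s.
#' @param settle_fraction trailing fraction averaged (default 0.5).
#' @return list with `value` (L/min), `steady` (logical), `slope` (L/min/s).
#' @export
measure_steady_backflow <- function(flow, dt = 1 / 200, settle_fraction = 0.5) {
  if (length(flow) < 2L)
    stop_trimorph("flow record is empty or too short", "trimorph_invalid_parameter")
  assert_scalar_num(dt, "dt", positive = TRUE)
  n <- length(flow)
  tail_idx <- seq.int(n - ceiling(settle_fraction * n) + 1L, n)
  value <- mean(flow[tail_idx])
  half <- seq.int(floor(n / 2) + 1L, n)
  tt <- (half - 1) * dt
  slope <- unname(coef(lm(flow[half] ~ tt))[2L])
  steady <- is.finite(slope) && abs(slope) <= 0.01 * max(abs(value), 1e-12)
  list(value = value, steady = steady, slope = slope)
}

#' All pulsatile indexes from one record
#'
#' @param wf a `flow_waveform_set`.
#' @param stroke_volume pump stroke volume, mL.
#' @param n_cycles cycles to average.
#' @return list with `TRF` (%), `CO` (L/min), `PRV` (mL), and the
#'   `averaged_cycle` used.
#' @export
compute_hemo_indexes <- function(wf, stroke_volume = 70, n_cycles = 10L) {
  cyc <- ensemble_average(wf, n_cycles = n_cycles)
  list(TRF = compute_trf(cyc, stroke_volume), CO = compute_co(cyc),
       PRV = compute_prv(cyc), cycle = cyc)
}
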