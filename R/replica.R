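## End-to-end cohort replica: synthesis -> measurement -> summary.
##
## Draws a paired fresh/defrosted cohort calibrated to the reference
## targets, builds a valve phantom, an RV phantom and waveform records per
## sample, runs the full measurement pipelines on them, and reports a
## Table-style summary plus recovery diagnostics (measured vs generator
## truth per sample). Directly sampled metrics: BF15, BF30, TRF, CO, PRV,
## Dmax, Dmin, Tvol, RVvol. L2D/L3D/A2D/A3D are geometrically determined by
## the phantom, so their per-sample truth is the phantom's quadrature
## ground truth.

FREE_METRICS <- c("BF15", "BF30", "TRF", "CO", "PRV",
                  "Dmax", "Dmin", "Tvol", "RVvol")
DERIVED_METRICS <- c("L2D", "L3D", "A2D", "A3D")

#' Replica run configuration
#'
#' @param n_samples paired samples per cohort.
#' @param seed master seed; the whole run is byte-reproducible given it.
#' @param paired_correlation within-pair correlation of the cohort sampler.
#' @param saddle_height annulus out-of-plane amplitude, mm.
#' @param rv_spacing voxel size of the RV phantoms, mm (0.7 keeps twenty
#'   segmentations fast; discretization error is ~0.1-0.3%).
#' @param rv_noise_sd RV phantom noise SD, intensity units.
#' @param n_cycles pulsatile cycles generated and averaged.
#' @param Rp Windkessel peripheral resistance, mmHg s/mL.
#' @param targets cohort calibration table (see [table1_targets()]).
#' @return An object of class `replica_config`.
#' @export
replica_config <- function(n_samples = 10L, seed = 1L, paired_correlation = 0.8,
                           saddle_height = 3.6, rv_spacing = 0.7,
                           rv_noise_sd = 5, n_cycles = 10L, Rp = 1.0,
                           targets = table1_targets()) {
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 paired_correlation = paired_correlation,
                 saddle_height = saddle_height, rv_spacing = rv_spacing,
                 rv_noise_sd = rv_noise_sd, n_cycles = as.integer(n_cycles),
                 Rp = Rp, targets = targets),
            class = "replica_config")
}

## physically admissible truth values for phantom construction
clamp_truths <- function(tr) {
  tr["BF15"] <- max(tr["BF15"], 0.02)
  tr["BF30"] <- max(tr["BF30"], 0.02)
  tr["TRF"] <- min(max(tr["TRF"], 0), 95)
  tr["PRV"] <- max(tr["PRV"], 0)
  tr["CO"] <- max(tr["CO"], 0.1)
  tr["Tvol"] <- max(tr["Tvol"], 0.3)
  dmx <- max(tr["Dmax"], tr["Dmin"], 10.2)
  dmn <- max(min(tr["Dmax"], tr["Dmin"]), 10)
  if (dmx - dmn < 0.2) dmx <- dmn + 0.2
  tr["Dmax"] <- dmx; tr["Dmin"] <- dmn
  tr["RVvol"] <- max(tr["RVvol"], 20)
  tr
}

## Measure one sample (one condition) end to end. Returns truth and
## measured values for all metrics.
measure_sample <- function(tr, cfg, sample_seed) {
  tr <- stats::setNames(as.numeric(tr), FREE_METRICS)
  a <- tr[["Dmax"]] / 2; b <- tr[["Dmin"]] / 2
  ann <- build_annulus("saddle", a_mm = a, b_mm = b,
                       saddle_height = cfg$saddle_height)
  ## calibrate the paraboloid depth so the quadrature tenting volume hits
  ## the sampled target (the planar closed form 2 Tvol / (pi a b) is only a
  ## starting point once the annulus is non-planar)
  h0 <- 2 * tr[["Tvol"]] * 1000 / (pi * a * b)
  tvol_at <- function(h)
    oracle_tenting_volume(ann, leaflet_spec(ann, "paraboloid",
                                            tenting_depth = h),
                          n_t = 512L, n_f = 128L) - tr[["Tvol"]]
  h <- stats::uniroot(tvol_at, lower = 1e-3, upper = 3 * h0 + 20,
                      tol = 1e-4)$root
  spec <- leaflet_spec(ann, "paraboloid", tenting_depth = h)
  truth_geo <- analytic_truth(ann, spec, n_quad = 2e4)
  morpho <- run_morphometry(spec)

  sv <- (tr[["CO"]] / 0.06 * 1 + tr[["PRV"]]) / (1 - tr[["TRF"]] / 100)
  settings <- pump_settings(heart_rate = 60, stroke_volume = sv, fs = 200)
  wf <- split_flows(settings, trf_target = tr[["TRF"]],
                    prv_target = tr[["PRV"]], n_cycles = cfg$n_cycles)
  wk <- windkessel_params(Rp = cfg$Rp)
  wf$pap <- simulate_windkessel(wk, wf$q_pulm, dt = 1 / settings$fs,
                                cycle_samples = samples_per_cycle(settings))
  hemo <- compute_hemo_indexes(wf, stroke_volume = sv,
                               n_cycles = cfg$n_cycles)

  bf <- vapply(c(BF15 = 15, BF30 = 30), function(dp) {
    key <- if (dp == 15) "BF15" else "BF30"
    om <- calibrate_orifice(tr[[key]], dp)
    rec <- rep(steady_backflow(om, dp), 400L)   # 2 s settled record
    measure_steady_backflow(rec, dt = 1 / 200)$value
  }, 0)

  base_ax <- c(50, 40, 22.2)
  scale <- (tr[["RVvol"]] / (4 / 3 * pi * prod(base_ax) / 1000))^(1 / 3)
  rv_spec <- rv_phantom_spec(base_ax * scale, noise_sd = cfg$rv_noise_sd,
                             seed = sample_seed)
  rv <- build_rv_phantom(rv_spec, spacing = cfg$rv_spacing)
  seg <- segment_rv(rv$volume, default_rv_thresholds(rv_spec),
                    seeds = matrix(rv_spec$center, 1L))

  ## geometric truths come from the quadrature oracle (for the sampled
  ## shape metrics they equal the sampled targets up to phantom algebra)
  truth <- c(BF15 = tr[["BF15"]], BF30 = tr[["BF30"]], TRF = tr[["TRF"]],
             CO = tr[["CO"]], PRV = tr[["PRV"]],
             Dmax = truth_geo$Dmax, Dmin = truth_geo$Dmin,
             Tvol = truth_geo$Tvol, RVvol = rv$true_volume,
             L2D = truth_geo$L2D, L3D = truth_geo$L3D,
             A2D = truth_geo$A2D, A3D = truth_geo$A3D)
  measured <- c(BF15 = unname(bf[["BF15"]]), BF30 = unname(bf[["BF30"]]),
                TRF = unname(hemo$TRF), CO = unname(hemo$CO),
                PRV = unname(hemo$PRV),
                Dmax = morpho$Dmax, Dmin = morpho$Dmin, Tvol = morpho$Tvol,
                RVvol = seg$volume_ml,
                L2D = morpho$L2D, L3D = morpho$L3D,
                A2D = morpho$A2D, A3D = morpho$A3D)
  list(truth = truth, measured = measured)
}

#' Run the full cohort replica
#'
#' @param config a [replica_config()].
#' @param outdir optional output directory; when given, writes
#'   `summary.csv`, `summary.md`, `measurements.csv` and `config.json`
#'   (every file embeds the config hash; outputs are byte-reproducible
#'   under a fixed seed).
#' @return An object of class `replica_report`: list with `config`, `hash`,
#'   `measurements` (long data.frame: metric, sample_id, condition, truth,
#'   measured), `summary` (a `cohort_summary` over the measured values) and
#'   `recovery` (per metric and condition, relative error of the recovered
#'   cohort mean against the generator-truth mean).
#' @export
run_replica <- function(config = replica_config(), outdir = NULL) {
  stopifnot(inherits(config, "replica_config"))
  hash <- config_hash(config[setdiff(names(config), "targets")])
  cc <- cohort_config(config$targets, n_samples = config$n_samples,
                      paired_correlation = config$paired_correlation,
                      seed = config$seed)
  cohort <- sample_cohort(cc)
  all_metrics <- c(FREE_METRICS, DERIVED_METRICS)
  rows <- list()
  for (i in seq_len(config$n_samples)) {
    for (cond in c("fresh", "defrosted")) {
      sub <- cohort[cohort$sample_id == i, ]
      tr <- stats::setNames(sub[[cond]][match(FREE_METRICS, sub$metric)],
                            FREE_METRICS)
      tr <- clamp_truths(tr)
      res <- tryCatch(
        measure_sample(tr, config,
                       sample_seed = config$seed + 1000L * i +
                         (cond == "defrosted") * 500L),
        error = function(e) stop_trimorph(
          sprintf("replica stage failed for sample %d (%s): %s",
                  i, cond, conditionMessage(e)),
          "trimorph_stage_failure"))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = all_metrics, sample_id = i, condition = cond,
        truth = unname(res$truth[all_metrics]),
        measured = unname(res$measured[all_metrics]),
        stringsAsFactors = FALSE)
    }
  }
  meas <- do.call(rbind, rows)

  units <- stats::setNames(config$targets$unit, config$targets$metric)
  pm_list <- lapply(all_metrics, function(m) {
    f <- meas[meas$metric == m & meas$condition == "fresh", ]
    d <- meas[meas$metric == m & meas$condition == "defrosted", ]
    paired_measurements(m, f$measured[order(f$sample_id)],
                        d$measured[order(d$sample_id)],
                        unit = unname(units[m]))
  })
  summary <- build_summary(pm_list)

  recovery <- do.call(rbind, lapply(all_metrics, function(m) {
    do.call(rbind, lapply(c("fresh", "defrosted"), function(cond) {
      sub <- meas[meas$metric == m & meas$condition == cond, ]
      data.frame(metric = m, condition = cond,
                 truth_mean = mean(sub$truth),
                 measured_mean = mean(sub$measured),
                 rel_err = abs(mean(sub$measured) - mean(sub$truth)) /
                   abs(mean(sub$truth)),
                 max_sample_rel_err = max(abs(sub$measured - sub$truth) /
                                            abs(sub$truth)),
                 stringsAsFactors = FALSE)
    }))
  }))

  report <- structure(list(config = config, hash = hash, measurements = meas,
                           summary = summary, recovery = recovery),
                      class = "replica_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cbind(summary, config_hash = hash),
              file.path(outdir, "summary.csv"), row.names = FALSE)
    writeLines(c(sprintf("<!-- config %s -->", hash), format_summary_md(summary)),
               file.path(outdir, "summary.md"))
    write.csv(cbind(meas, config_hash = hash),
              file.path(outdir, "measurements.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(config[setdiff(names(config), "targets")], list(config_hash = hash)),
      file.path(outdir, "config.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.replica_report <- function(x, ...) {
  cat(sprintf("<replica_report> %d paired samples, seed %d, config %s\n",
              x$config$n_samples, x$config$seed, substr(x$hash, 1, 8)))
  cat(sprintf("  worst cohort-mean recovery error: %.2f%% (%s, %s)\n",
              100 * max(x$recovery$rel_err),
              x$recovery$metric[which.max(x$recovery$rel_err)],
              x$recovery$condition[which.max(x$recovery$rel_err)]))
  invisible(x)
}
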