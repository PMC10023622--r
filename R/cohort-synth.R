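## Paired fresh/defrosted cohort synthesis.
##
## The packaged default targets carry the reported mean and SD of each
## quantitative index in the fresh and defrosted conditions of the ex vivo
## porcine model (ten hearts, measured fresh and again after freeze-thaw).
## Per metric, a sample's (fresh, defrosted) truth pair is drawn from a
## bivariate normal with the configured marginals and a configurable
## within-pair correlation (the study reports only marginals, so the
## correlation is a free parameter of the stated world; default 0.8).

#' Reference cohort calibration targets
#'
#' Mean and SD of every quantitative index in the fresh and defrosted
#' conditions, used to calibrate the synthetic cohort generator.
#'
#' @return data.frame with columns `metric`, `unit`, `fresh_mean`,
#'   `fresh_sd`, `defrosted_mean`, `defrosted_sd`.
#' @export
table1_targets <- function() {
  data.frame(
    metric = c("BF15", "BF30", "TRF", "CO", "PRV",
               "Dmax", "Dmin", "L2D", "L3D", "A2D", "A3D", "Tvol", "RVvol"),
    unit = c("L/min", "L/min", "%", "L/min", "mL",
             "mm", "mm", "mm", "mm", "mm^2", "mm^2", "mL", "mL"),
    fresh_mean     = c(0.4, 1.0, 67.1, 1.7, 7.9,
                       50.2, 43.1, 149.2, 152.8, 1735.9, 1808.0, 6.0, 185.8),
    fresh_sd       = c(0.3, 0.5, 8.5, 0.9, 2.1,
                       3.6, 3.5, 10.0, 10.1, 234.1, 238.0, 0.8, 40.8),
    defrosted_mean = c(1.7, 3.5, 84.0, 0.9, 8.3,
                       51.7, 45.1, 153.7, 156.9, 1861.5, 1919.7, 13.3, 202.0),
    defrosted_sd   = c(0.9, 1.6, 4.0, 0.9, 2.6,
                       2.4, 3.6, 8.1, 7.6, 210.7, 197.9, 4.5, 36.4),
    stringsAsFactors = FALSE)
}

#' Fresh / defrosted cohort target columns
#'
#' Convenience accessors for the two columns of [table1_targets()].
#' @return data.frame with `metric`, `unit`, `mean`, `sd`.
#' @export
fresh_cohort <- function() {
  t1 <- table1_targets()
  data.frame(metric = t1$metric, unit = t1$unit,
             mean = t1$fresh_mean, sd = t1$fresh_sd, stringsAsFactors = FALSE)
}

#' @rdname fresh_cohort
#' @export
defrosted_cohort <- function() {
  t1 <- table1_targets()
  data.frame(metric = t1$metric, unit = t1$unit,
             mean = t1$defrosted_mean, sd = t1$defrosted_sd,
             stringsAsFactors = FALSE)
}

#' Cohort generator configuration
#'
#' @param targets data.frame in the layout of [table1_targets()] (any subset
#'   of metrics).
#' @param n_samples number of paired samples (hearts), >= 2.
#' @param paired_correlation within-pair fresh/defrosted correlation in
#'   `[0, 1)`.
#' @param seed RNG seed; the sampler is fully deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(targets = table1_targets(), n_samples = 10L,
                          paired_correlation = 0.8, seed = 1L) {
  need <- c("metric", "fresh_mean", "fresh_sd", "defrosted_mean", "defrosted_sd")
  if (!is.data.frame(targets) || !all(need %in% names(targets)))
    stop_trimorph("`targets` must carry metric, fresh/defrosted mean and sd columns",
                  "trimorph_invalid_parameter")
  if (any(targets$fresh_sd < 0) || any(targets$defrosted_sd < 0))
    stop_trimorph("target SDs must be >= 0", "trimorph_invalid_parameter")
  if (!is.numeric(n_samples) || n_samples < 2)
    stop_trimorph("n_samples must be >= 2", "trimorph_invalid_parameter")
  if (paired_correlation < 0 || paired_correlation >= 1)
    stop_trimorph("paired_correlation must be in [0, 1)", "trimorph_invalid_parameter")
  structure(list(targets = targets, n_samples = as.integer(n_samples),
                 paired_correlation = paired_correlation,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw a paired synthetic cohort
#'
#' For each metric, draws `n_samples` (fresh, defrosted) ground-truth pairs
#' from a bivariate normal with the configured marginal means/SDs and
#' within-pair correlation. The sampler is mean-unbiased: no clamping is
#' applied here (physical floors are the caller's concern).
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `metric`, `sample_id`, `fresh`,
#'   `defrosted` (long over metrics, `n_samples` rows per metric).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  t1 <- config$targets
  rho <- config$paired_correlation
  n <- config$n_samples
  with_seed(config$seed, {
    out <- lapply(seq_len(nrow(t1)), function(i) {
      zf <- rnorm(n); z2 <- rnorm(n)
      fresh <- t1$fresh_mean[i] + t1$fresh_sd[i] * zf
      defr <- t1$defrosted_mean[i] +
        t1$defrosted_sd[i] * (rho * zf + sqrt(1 - rho^2) * z2)
      data.frame(metric = t1$metric[i], sample_id = seq_len(n),
                 fresh = fresh, defrosted = defr, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
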