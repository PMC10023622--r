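## Paired fresh-vs-defrosted cohort statistics.
##
## Normality is screened per condition with Shapiro-Wilk, differences are
## tested with a two-sided paired t-test, and the headline effect size is
## the mean per-sample percent variation: mean_i of
## 100 (defrosted_i - fresh_i) / fresh_i. Averaging per-sample relative
## changes (rather than taking the relative change of the means) is the only
## reading consistent with heterogeneous samples whose baseline spans an
## order of magnitude, and is deliberately scale-invariant per sample.

#' Paired measurements of one metric
#'
#' @param metric metric name.
#' @param fresh,defrosted numeric vectors of equal length >= 2, no missing
#'   values.
#' @param sample_ids optional identifiers.
#' @param unit optional unit string.
#' @return An object of class `paired_measurements`.
#' @export
paired_measurements <- function(metric, fresh, defrosted,
                                sample_ids = seq_along(fresh), unit = "") {
  if (length(fresh) != length(defrosted) || length(fresh) < 2L)
    stop_trimorph("fresh and defrosted must have equal length >= 2",
                  "trimorph_invalid_parameter")
  if (anyNA(fresh) || anyNA(defrosted))
    stop_trimorph("missing values are not allowed within pairs",
                  "trimorph_invalid_parameter")
  structure(list(metric = metric, fresh = as.numeric(fresh),
                 defrosted = as.numeric(defrosted),
                 sample_ids = sample_ids, unit = unit),
            class = "paired_measurements")
}

#' Shapiro-Wilk normality check
#'
#' @param values numeric vector, 3 <= n <= 50, non-constant.
#' @return list with `W` and `p`.
#' @export
check_normality <- function(values) {
  n <- length(values)
  if (n < 3L || n > 50L)
    stop_trimorph("Shapiro-Wilk requires 3 <= n <= 50 here", "trimorph_invalid_parameter")
  if (sd(values) < 1e-12 * max(abs(values), 1))
    stop_trimorph("values are (near-)constant", "trimorph_degenerate_data")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the pair differences `d = defrosted -
#' fresh`, df = n - 1, two-sided p from Student's t.
#'
#' @param pairs a [paired_measurements()] object.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  d <- pairs$defrosted - pairs$fresh
  n <- length(d)
  s <- sd(d)
  if (s < 1e-12 * max(abs(d), 1))
    stop_trimorph("pair differences have zero variance", "trimorph_degenerate_data")
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1), df = n - 1,
       mean_diff = mean(d))
}

#' Mean per-sample percent variation
#'
#' @param pairs a [paired_measurements()] object; fresh values must be
#'   nonzero.
#' @return mean of `100 * (defrosted - fresh) / fresh`, percent.
#' @export
mean_variation <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  if (any(abs(pairs$fresh) < 1e-12))
    stop_trimorph("mean variation is undefined for zero fresh values",
                  "trimorph_degenerate_data")
  mean(100 * (pairs$defrosted - pairs$fresh) / pairs$fresh)
}

#' Build a cohort summary table
#'
#' One row per metric, in input order: fresh and defrosted mean and SD, mean
#' per-sample variation, paired-t p-value.
#'
#' @param metrics list of [paired_measurements()] objects.
#' @return An object of class `cohort_summary` (a data.frame with columns
#'   `metric`, `unit`, `fresh_mean`, `fresh_sd`, `defrosted_mean`,
#'   `defrosted_sd`, `mean_variation_pct`, `p_value`).
#' @export
build_summary <- function(metrics) {
  if (length(metrics) == 0L)
    stop_trimorph("no metrics supplied", "trimorph_invalid_parameter")
  rows <- lapply(metrics, function(pm) {
    stopifnot(inherits(pm, "paired_measurements"))
    tt <- tryCatch(paired_t_test(pm), trimorph_degenerate_data = function(e) NULL)
    data.frame(metric = pm$metric, unit = pm$unit,
               fresh_mean = mean(pm$fresh), fresh_sd = sd(pm$fresh),
               defrosted_mean = mean(pm$defrosted), defrosted_sd = sd(pm$defrosted),
               mean_variation_pct = mean_variation(pm),
               p_value = if (is.null(tt)) NA_real_ else tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Render a cohort summary as Markdown
#'
#' @param summary a `cohort_summary`.
#' @return character vector of Markdown lines.
#' @export
format_summary_md <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  fmt_p <- function(p) ifelse(is.na(p), "-",
                              ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p)))
  c("| Metric | Fresh | Defrosted | Mean variation (%) | p-value |",
    "|---|---|---|---|---|",
    sprintf("| %s (%s) | %.1f ± %.1f | %.1f ± %.1f | %.1f | %s |",
            summary$metric, summary$unit,
            summary$fresh_mean, summary$fresh_sd,
            summary$defrosted_mean, summary$defrosted_sd,
            summary$mean_variation_pct, fmt_p(summary$p_value)))
}

#' Read paired measurements from a long-format CSV
#'
#' Columns `metric, sample_id, condition, value` with condition `fresh` or
#' `defrosted`.
#'
#' @param path CSV path.
#' @return list of [paired_measurements()] objects, one per metric.
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("metric", "sample_id", "condition", "value")
  if (!all(need %in% names(df)))
    stop_trimorph("measurements CSV needs metric, sample_id, condition, value",
                  "trimorph_io_error")
  lapply(unique(df$metric), function(m) {
    sub <- df[df$metric == m, ]
    f <- sub[sub$condition == "fresh", ]
    d <- sub[sub$condition == "defrosted", ]
    f <- f[order(f$sample_id), ]; d <- d[order(d$sample_id), ]
    if (!identical(f$sample_id, d$sample_id))
      stop_trimorph(sprintf("metric %s has unmatched fresh/defrosted samples", m),
                    "trimorph_invalid_parameter")
    paired_measurements(m, f$value, d$value, sample_ids = f$sample_id)
  })
}
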