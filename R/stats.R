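# Group comparisons and inhibition quantification.
#
# The t tests delegate to stats::t.test (pooled-variance Student form by
# default, matching the equal-SD assumption stated for the assay; Welch is
# available behind var_equal = FALSE). Degenerate zero-variance inputs, on
# which t.test errors, follow the documented conventions: equal means ->
# t = 0, p = 1; unequal means -> t = +/-Inf, p = 0.

ppa_test_result <- function(statistic, df, p_value, ci95, estimate,
                            n_a, n_b, kind) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 ci95 = ci95, estimate = estimate, n_a = n_a, n_b = n_b,
                 kind = kind),
            class = "ppa_test")
}

#' @export
print.ppa_test <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4g, df = %s, p = %.4g\n",
              if (x$kind == "paired") "Paired"
              else if (x$kind == "unpaired_equal_var") "Two-sample (pooled)"
              else "Two-sample (Welch)",
              x$statistic, format(x$df, digits = 4), x$p_value))
  cat(sprintf("  mean difference %.4g, 95%% CI [%.4g, %.4g] (n = %d, %d)\n",
              x$estimate, x$ci95[1L], x$ci95[2L], x$n_a, x$n_b))
  invisible(x)
}

#' Unpaired two-sample t test on activity rates
#'
#' Student's pooled-variance form by default (`df = n_a + n_b - 2`), with a
#' two-sided p value and the 95% confidence interval of the mean difference
#' `a - b`.
#'
#' @param a,b Numeric rate vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student test (`TRUE`, default) or Welch.
#' @return A `ppa_test` object: `statistic`, `df`, `p_value`, `ci95`,
#'   `estimate` (mean of `a` minus mean of `b`), `n_a`, `n_b`, `kind`.
#' @export
unpaired_t_test <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    abort_input("both groups need at least 2 observations")
  if (anyNA(a) || anyNA(b) || any(is.infinite(c(a, b))))
    abort_input("rates must be finite and non-missing")
  kind <- if (var_equal) "unpaired_equal_var" else "unpaired_welch"
  diff <- mean(a) - mean(b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (diff == 0)
      return(ppa_test_result(0, length(a) + length(b) - 2L, 1, c(0, 0), 0,
                             length(a), length(b), kind))
    return(ppa_test_result(sign(diff) * Inf, length(a) + length(b) - 2L, 0,
                           c(diff, diff), diff, length(a), length(b), kind))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal, conf.level = 0.95)
  ppa_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  as.numeric(tt$conf.int), diff, length(a), length(b), kind)
}

#' Paired t test on matched activity rates
#'
#' One-sample t test on the paired differences `x - y` (`df = n - 1`),
#' two-sided, with the 95% confidence interval of the mean difference. Pairs
#' must be aligned by sample.
#'
#' @param x,y Numeric vectors of equal length >= 2, matched elementwise.
#' @return A `ppa_test` object (see [unpaired_t_test()]).
#' @export
paired_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    abort_pairing("paired vectors have different lengths")
  if (length(x) < 2L) abort_input("need at least 2 pairs")
  if (anyNA(x) || anyNA(y) || any(is.infinite(c(x, y))))
    abort_input("rates must be finite and non-missing")
  d <- x - y
  if (stats::var(d) == 0) {
    if (d[1L] == 0)
      return(ppa_test_result(0, length(d) - 1L, 1, c(0, 0), 0,
                             length(x), length(y), "paired"))
    return(ppa_test_result(sign(d[1L]) * Inf, length(d) - 1L, 0,
                           c(d[1L], d[1L]), d[1L], length(x), length(y), "paired"))
  }
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = 0.95)
  ppa_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  as.numeric(tt$conf.int), mean(d), length(x), length(y), "paired")
}

#' Percent inhibition relative to control
#'
#' `100 * (1 - inhibited / control)`. Negative values (activation) are
#' reported as-is; non-positive control rates make the quantity undefined and
#' yield `NA`.
#'
#' @param control_rate,inhibited_rate Numeric rate vectors (recycled).
#' @return Numeric vector of percent inhibition.
#' @export
percent_inhibition <- function(control_rate, inhibited_rate) {
  out <- 100 * (1 - inhibited_rate / control_rate)
  out[!is.na(control_rate) & control_rate <= 0] <- NA_real_
  out
}

#' Summarize a paired inhibitor/control comparison
#'
#' @param control_rate,inhibited_rate Per-sample rates under control and
#'   inhibitor conditions, aligned by sample.
#' @param sample_id Optional sample ids for the per-sample table.
#' @return An `inhibition_result`: `mean_percent_inhibition`, `per_sample`
#'   (data frame of rates and percent inhibition), and `test` (paired t test
#'   of control vs inhibited rates).
#' @export
inhibition_summary <- function(control_rate, inhibited_rate, sample_id = NULL) {
  if (length(control_rate) != length(inhibited_rate))
    abort_pairing("control and inhibited rate vectors differ in length")
  if (is.null(sample_id)) sample_id <- sprintf("S%02d", seq_along(control_rate))
  pct <- percent_inhibition(control_rate, inhibited_rate)
  structure(
    list(mean_percent_inhibition = mean(pct, na.rm = TRUE),
         per_sample = data.frame(sample_id = sample_id,
                                 control_rate = control_rate,
                                 inhibited_rate = inhibited_rate,
                                 percent_inhibition = pct,
                                 stringsAsFactors = FALSE),
         test = paired_t_test(control_rate, inhibited_rate)),
    class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("Inhibition: mean %.1f%% of control activity blocked (n = %d)\n",
              x$mean_percent_inhibition, nrow(x$per_sample)))
  print(x$test)
  invisible(x)
}

#' Quantify inhibition from a paired simulated experiment
#'
#' Runs the kinetics pipeline (normalization, intrinsic subtraction, linear
#' phase, OLS slope, replicate aggregation) separately on the control and
#' inhibitor wells of a paired experiment and summarizes per-sample percent
#' inhibition.
#'
#' @param x A `ppa_inhibition_sim` from [simulate_inhibition_experiment()].
#' @param control An [activity_control()].
#' @return An [inhibition_summary()] result.
#' @export
inhibition_analysis <- function(x, control = activity_control()) {
  stopifnot(inherits(x, "ppa_inhibition_sim"))
  ref <- reference_value(x$plates, control$reference_plate)
  rates <- lapply(x$plates, function(run) {
    f <- plate_normalization_factor(run, ref)
    run <- normalize_plate(run, f$factor)
    intr <- plate_traces(run, "intrinsic")[[1L]]
    dig <- plate_traces(run, "digestion")
    cond <- vapply(dig, function(tr) tr$meta$condition, character(1))
    slope_of <- function(tr) {
      corrected <- subtract_intrinsic(tr, intr)
      win <- detect_linear_phase(corrected, control$window)
      fit_slope(corrected, win)$rate_rfu_per_min
    }
    data.frame(sample_id = intr$sample_id,
               control_rate = aggregate_replicates(
                 vapply(dig[cond == "control"], slope_of, numeric(1)))$mean,
               inhibited_rate = aggregate_replicates(
                 vapply(dig[cond == "inhibitor"], slope_of, numeric(1)))$mean,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rates)
  inhibition_summary(df$control_rate, df$inhibited_rate, df$sample_id)
}
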