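# Independent oracles: every reference computation here is coded separately
# from the package internals (lm() instead of the package's closed-form OLS,
# explicit pairwise loops instead of rank formulas, textbook closed forms for
# the pooled t test), so agreement is a genuine two-route check.

# OLS slope/stderr/R^2 via lm().
oracle_slope_lm <- function(t, y) {
  m <- stats::lm(y ~ t)
  s <- summary(m)
  list(slope = unname(stats::coef(m)[2L]),
       stderr = unname(s$coefficients[2L, 2L]),
       r_squared = s$r.squared)
}

# Textbook pooled-variance Student t with 95% CI.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mean(a) - mean(b)) / se
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       ci = (mean(a) - mean(b)) + c(-1, 1) * stats::qt(0.975, df) * se)
}

# One-sample t on paired differences.
oracle_paired_t <- function(x, y) {
  d <- x - y; n <- length(d)
  se <- stats::sd(d) / sqrt(n)
  t <- mean(d) / se
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       ci = mean(d) + c(-1, 1) * stats::qt(0.975, n - 1) * se)
}

# Mann-Whitney AUC by explicit enumeration of all (positive, negative) pairs.
oracle_auc_pairs <- function(scores, labels, positive) {
  p <- scores[labels == positive]
  n <- scores[labels != positive]
  s <- 0
  for (x in p) for (y in n) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(n))
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1L]) / 2)
}

# Exhaustive linear-window search applying the same acceptance rule as the
# detector over ALL candidate windows, then choosing the longest (ties:
# earliest). Implemented with lm() and explicit loops.
oracle_window <- function(trace, opt = linear_phase_options()) {
  ok <- !is.na(trace$rfu)
  t <- trace$time_min[ok]; y <- trace$rfu[ok]
  region <- which(t <= opt$t_max_window + 1e-9)
  if (length(region) < opt$min_points) region <- seq_len(opt$min_points)
  t0 <- t[region]; y0 <- y[region]; m <- length(t0)
  full <- stats::lm(y0 ~ t0)
  if (abs(stats::coef(full)[2L]) < opt$activity_floor_rfu_per_min)
    return(list(t_start = t0[1L], t_end = t0[m], low_activity = TRUE))
  n_all <- length(y)
  k <- max(4L, n_all %/% 3L)
  tail_y <- y[seq.int(n_all - min(k, n_all) + 1L, n_all)]
  noise <- if (length(tail_y) >= 3L) stats::sd(diff(tail_y)) else 0
  acc <- list()
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j - i + 1L < opt$min_points) next
    if (t0[j] - t0[i] < opt$t_min_window - 1e-9) next
    fit <- stats::lm(y0[i:j] ~ t0[i:j])
    dev <- max(abs(stats::resid(fit)))
    span <- diff(range(y0[i:j]))
    if (dev <= opt$linearity_tol * span + 3 * noise)
      acc[[length(acc) + 1L]] <- c(len = j - i + 1L, start = i,
                                   t_start = t0[i], t_end = t0[j])
  }
  if (!length(acc))
    return(list(t_start = t0[1L], t_end = t0[opt$min_points], low_activity = FALSE))
  A <- do.call(rbind, acc)
  A <- A[order(-A[, "len"], A[, "start"]), , drop = FALSE]
  list(t_start = unname(A[1L, "t_start"]), t_end = unname(A[1L, "t_end"]),
       low_activity = FALSE)
}

# Multiply every read of every well on a plate by k (simulates a different
# detector gain).
scale_plate <- function(plate, k) {
  plate$traces <- lapply(plate$traces, function(tr) {
    tr$rfu <- tr$rfu * k
    tr
  })
  plate
}

# Small fully-specified study config used by several suites.
tiny_config <- function(..., seed = 11) {
  sim_config(cohorts = c(HC = 2L, CD = 2L),
             ph_levels = 7.5, replicates = 2L, seed = seed, ...)
}
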