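# Plate normalization and linear-phase rate estimation.

#' Reference value for plate normalization
#'
#' The reference value is the mean fluorescence of the empty (buffer-only)
#' wells of a designated reference plate; every plate's normalization factor
#' is computed against it.
#'
#' @param runs List of [plate_run()] objects.
#' @param reference_plate Plate id of the designated reference; `NULL` picks
#'   the plate flagged `is_reference_plate`, or failing that the first plate
#'   in input order.
#' @return A single RFU value.
#' @export
reference_value <- function(runs, reference_plate = NULL) {
  if (inherits(runs, "plate_run")) runs <- list(runs)
  ids <- vapply(runs, function(r) r$plate_id, character(1))
  ref <- if (!is.null(reference_plate)) {
    i <- match(reference_plate, ids)
    if (is.na(i)) abort_config(sprintf("reference plate %s not found", reference_plate))
    runs[[i]]
  } else {
    flagged <- which(vapply(runs, function(r) isTRUE(r$is_reference_plate), logical(1)))
    runs[[if (length(flagged)) flagged[1L] else 1L]]
  }
  reads <- empty_well_reads(ref)
  reads <- reads[!is.na(reads)]
  if (!length(reads))
    abort_layout(sprintf("reference plate %s has no empty-well reads", ref$plate_id))
  mean(reads)
}

#' Normalization factor of one plate
#'
#' `factor = mean(empty-well RFU of the plate) / reference_value`. Dividing a
#' plate's reads by its factor puts all plates on the reference plate's gain
#' scale.
#'
#' @param plate A [plate_run()].
#' @param reference_value Mean empty-well RFU of the designated reference
#'   plate (> 0); see [reference_value()].
#' @return A one-row data frame: `plate_id`, `factor`, `reference_value`,
#'   `empty_well_mean`, `n_empty_wells`.
#' @export
plate_normalization_factor <- function(plate, reference_value) {
  stopifnot(inherits(plate, "plate_run"))
  if (!is_number(reference_value) || reference_value <= 0)
    abort_input("'reference_value' must be a positive number")
  reads <- empty_well_reads(plate)
  reads <- reads[!is.na(reads)]
  if (!length(reads))
    abort_layout(sprintf("plate %s has no empty-well reads; cannot normalize", plate$plate_id))
  m <- mean(reads)
  data.frame(plate_id = plate$plate_id, factor = m / reference_value,
             reference_value = reference_value, empty_well_mean = m,
             n_empty_wells = sum(plate_roles(plate) == "empty"),
             stringsAsFactors = FALSE)
}

#' Divide every read of a plate by its normalization factor
#'
#' @param plate A [plate_run()].
#' @param factor Normalization factor (> 0), either the number or the row
#'   returned by [plate_normalization_factor()].
#' @return The normalized [plate_run()]; the factor is recorded in the
#'   plate's and every trace's metadata.
#' @export
normalize_plate <- function(plate, factor) {
  stopifnot(inherits(plate, "plate_run"))
  if (is.data.frame(factor)) factor <- factor$factor
  if (!is_number(factor) || factor <= 0)
    abort_input("'factor' must be a positive number")
  plate$traces <- lapply(plate$traces, function(tr) {
    tr$rfu <- tr$rfu / factor
    tr$meta$normalization_factor <- factor
    tr
  })
  plate$meta$normalization_factor <- factor
  plate
}

#' Options for linear-phase detection
#'
#' @param t_min_window Minimum window duration in minutes.
#' @param t_max_window Upper end (minutes) of the region in which the linear
#'   phase is sought; windows live inside `[0, t_max_window]`.
#' @param min_points Minimum reads per window.
#' @param linearity_tol Relative tolerance: a window is accepted when the
#'   maximum absolute deviation of its reads from their own least-squares
#'   line is at most `linearity_tol * RFU span of the window + 3 * noise`,
#'   where the noise scale is the SD of first differences of the trace tail.
#' @param activity_floor_rfu_per_min Slope magnitude below which a trace is
#'   treated as flat (`low_activity`) and given the default window.
#' @return A `linear_phase_options` list.
#' @export
linear_phase_options <- function(t_min_window = 5, t_max_window = 20,
                                 min_points = 4L, linearity_tol = 0.02,
                                 activity_floor_rfu_per_min = 0.5) {
  if (!is_number(t_max_window) || t_max_window <= 0)
    abort_input("'t_max_window' must be > 0")
  min_points <- as.integer(min_points)
  if (is.na(min_points) || min_points < 3L)
    abort_input("'min_points' must be >= 3")
  structure(list(t_min_window = t_min_window, t_max_window = t_max_window,
                 min_points = min_points, linearity_tol = linearity_tol,
                 activity_floor_rfu_per_min = activity_floor_rfu_per_min),
            class = "linear_phase_options")
}

# Noise scale of a trace: SD of first differences over the tail (the last
# max(4, floor(n/3)) reads), where the curve is flattest.
tail_noise_estimate <- function(trace) {
  rfu <- trace$rfu[!is.na(trace$rfu)]
  n <- length(rfu)
  k <- max(4L, n %/% 3L)
  tail_rfu <- rfu[seq.int(n - min(k, n) + 1L, n)]
  if (length(tail_rfu) < 3L) return(0)
  stats::sd(diff(tail_rfu))
}

#' Detect the linear phase of a corrected kinetic trace
#'
#' Initial reaction rates must be read off the early, linear part of the
#' progress curve, before substrate depletion bends it. The detector
#' enumerates contiguous read windows starting within `[0, t_max_window]`
#' and wholly contained in it, ordered by decreasing length and then earliest
#' start, and accepts the first window that passes the linearity rule of
#' [linear_phase_options()]. Flat traces (full-window slope magnitude below
#' `activity_floor_rfu_per_min`) get the default window `[0, t_max_window]`
#' with `low_activity = TRUE` -- an R-squared rule would be undefined there.
#' If no window passes, the earliest shortest window is returned.
#'
#' @param trace A corrected [kinetic_trace()].
#' @param options A [linear_phase_options()].
#' @return A one-row data frame: `t_start`, `t_end`, `n_points`, `r_squared`
#'   (`NA` for flat windows), `low_activity`.
#' @export
detect_linear_phase <- function(trace, options = linear_phase_options()) {
  stopifnot(inherits(trace, "kinetic_trace"))
  ok <- !is.na(trace$rfu)
  t <- trace$time_min[ok]
  y <- trace$rfu[ok]
  if (length(t) < options$min_points)
    abort_input(sprintf("trace %s/%s has %d usable reads; need >= %d",
                        trace$plate_id, trace$well_id, length(t), options$min_points))
  in_region <- which(t <= options$t_max_window + 1e-9)
  if (length(in_region) < options$min_points)
    in_region <- seq_len(options$min_points)
  t0 <- t[in_region]; y0 <- y[in_region]
  m <- length(t0)

  # Flat-trace short circuit: slope of the full candidate region.
  full <- ols_line(t0, y0)
  if (abs(full$slope) < options$activity_floor_rfu_per_min) {
    return(window_row(t0[1L], t0[m], m, NA_real_, TRUE))
  }

  noise <- tail_noise_estimate(trace)
  cands <- candidate_windows(m, options$min_points)
  for (k in seq_len(nrow(cands))) {
    i <- cands$start[k]; j <- cands$end[k]
    if (t0[j] - t0[i] < options$t_min_window - 1e-9) next
    tw <- t0[i:j]; yw <- y0[i:j]
    fit <- ols_line(tw, yw)
    dev <- max(abs(yw - (fit$intercept + fit$slope * tw)))
    span <- diff(range(yw))
    if (dev <= options$linearity_tol * span + 3 * noise) {
      return(window_row(tw[1L], tw[length(tw)], length(tw), fit$r_squared, FALSE))
    }
  }
  # Fallback: earliest shortest window.
  i <- 1L; j <- options$min_points
  fit <- ols_line(t0[i:j], y0[i:j])
  window_row(t0[i], t0[j], j - i + 1L, fit$r_squared, FALSE)
}

# Contiguous index windows ordered by decreasing length, then earliest start.
candidate_windows <- function(n, min_points) {
  out <- do.call(rbind, lapply(seq.int(n, min_points), function(len) {
    starts <- seq_len(n - len + 1L)
    data.frame(start = starts, end = starts + len - 1L)
  }))
  out
}

window_row <- function(t_start, t_end, n_points, r_squared, low_activity) {
  data.frame(t_start = t_start, t_end = t_end, n_points = n_points,
             r_squared = r_squared, low_activity = low_activity)
}

# Closed-form simple OLS used throughout (avoids lm() overhead per well).
ols_line <- function(t, y) {
  n <- length(t)
  tb <- mean(t); yb <- mean(y)
  sxx <- sum((t - tb)^2)
  slope <- sum((t - tb) * (y - yb)) / sxx
  intercept <- yb - slope * tb
  resid <- y - intercept - slope * t
  sse <- sum(resid^2)
  sst <- sum((y - yb)^2)
  stderr <- if (n > 2L) sqrt(sse / (n - 2L) / sxx) else NA_real_
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  list(slope = slope, intercept = intercept, stderr = stderr,
       r_squared = r2, residuals = resid)
}

#' Ordinary-least-squares rate over a window
#'
#' Fits `RFU ~ time` over the reads inside the window and returns the slope
#' in RFU/min (the enzymatic rate), its standard error, and R-squared. The
#' intercept is discarded: rates are offset-invariant by construction.
#'
#' @param trace A [kinetic_trace()].
#' @param window A window row from [detect_linear_phase()] (or any list with
#'   `t_start`, `t_end`).
#' @return A one-row data frame: `rate_rfu_per_min`, `stderr`, `r_squared`,
#'   `n_points`.
#' @export
fit_slope <- function(trace, window) {
  stopifnot(inherits(trace, "kinetic_trace"))
  ok <- !is.na(trace$rfu) &
    trace$time_min >= window$t_start - 1e-9 &
    trace$time_min <= window$t_end + 1e-9
  t <- trace$time_min[ok]; y <- trace$rfu[ok]
  if (length(t) < 3L)
    abort_input("window contains fewer than 3 reads")
  if (diff(range(t)) == 0)
    abort_input("degenerate window: all reads at the same timepoint")
  fit <- ols_line(t, y)
  data.frame(rate_rfu_per_min = fit$slope, stderr = fit$stderr,
             r_squared = fit$r_squared, n_points = length(t))
}

#' Aggregate replicate rates
#'
#' @param slopes Numeric vector of replicate rates (RFU/min).
#' @return A one-row data frame: arithmetic `mean`, sample `sd` (n-1
#'   denominator; `NA` for a single replicate, by policy, not 0), and `n`.
#' @export
aggregate_replicates <- function(slopes) {
  slopes <- slopes[!is.na(slopes)]
  if (!length(slopes)) abort_input("no replicate rates to aggregate")
  data.frame(mean = mean(slopes),
             sd = if (length(slopes) > 1L) stats::sd(slopes) else NA_real_,
             n = length(slopes))
}
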