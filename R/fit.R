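# The central estimator: plates + sample sheet -> per-sample activity rates.

#' Control parameters for the activity fit
#'
#' @param qc A [qc_policy()] deciding intrinsic-fluorescence exclusions.
#' @param window [linear_phase_options()] for linear-phase detection.
#' @param reference_plate Plate id of the normalization reference; `NULL`
#'   uses the flagged reference plate or the first plate in input order.
#' @param drop_excluded Whether QC-excluded samples are dropped from the
#'   activity matrix (`TRUE`, default) or kept as all-missing rows. Excluded
#'   samples always remain, flagged, in the audit tables.
#' @return An `activity_control` list.
#' @export
activity_control <- function(qc = qc_policy(), window = linear_phase_options(),
                             reference_plate = NULL, drop_excluded = TRUE) {
  stopifnot(inherits(qc, "qc_policy"), inherits(window, "linear_phase_options"))
  structure(list(qc = qc, window = window, reference_plate = reference_plate,
                 drop_excluded = isTRUE(drop_excluded)),
            class = "activity_control")
}

#' Fit per-sample protease activity rates from kinetic plates
#'
#' The core model of the package. For every digestion well the observed
#' progress curve is modelled as plate background plus sample intrinsic
#' fluorescence plus linear early-phase product formation, all scaled by a
#' plate gain:
#' the fit (i) divides each plate's reads by its empty-well normalization
#' factor, (ii) subtracts the sample's (normalized) intrinsic trace,
#' (iii) locates the linear phase of the corrected curve, and (iv) estimates
#' the rate in RFU/min by ordinary least squares over that window, then
#' aggregates replicate wells into per-(sample, substrate, pH) activity
#' records (mean, SD, n). Samples failing intrinsic-fluorescence QC are
#' flagged and withheld from downstream statistics. Steps (i) and (ii)
#' commute within a plate; normalizing raw traces rather than fitted slopes
#' is equivalent for OLS slopes and is the order fixed here.
#'
#' @param runs List of [plate_run()] objects (e.g. from
#'   [read_kinetic_table()] or [simulate_study()]`$plates`).
#' @param sheet Sample sheet data frame (`sample_id`, `cohort`, optional
#'   `phase`).
#' @param panel Substrate panel; defaults to the built-in 14-substrate panel.
#' @param control An [activity_control()].
#' @return An object of class `activity_fit` with components `records`
#'   (per-(sample, substrate, pH) rates), `well_fits` (per-well slopes and
#'   windows), `qc` (per-sample flags), `norm_factors`, `reference_value`,
#'   `matrix` (samples x (substrate, pH), see [build_activity_matrix()]),
#'   `issues` (layout problems found), `sheet`, `panel`, `control`.
#'   Methods: [print()], [summary()], [coef()] (the activity matrix),
#'   [residuals()] (per-read OLS residuals), [plot()] (cohort-profile
#'   heatmap).
#' @examples
#' cfg <- sim_config(cohorts = c(HC = 2, CD = 2), ph_levels = 7.5,
#'                   replicates = 2, seed = 42)
#' sim <- simulate_study(cfg)
#' fit <- fit_activity(sim$plates, sim$sheet, cfg$panel)
#' head(fit$records)
#' @export
fit_activity <- function(runs, sheet, panel = load_substrate_panel(),
                         control = activity_control()) {
  if (inherits(runs, "plate_run")) runs <- list(runs)
  stopifnot(inherits(control, "activity_control"))
  sheet <- validate_sample_sheet(sheet)
  panel <- validate_substrate_panel(as.data.frame(panel))
  issues <- validate_layout(runs, sheet, panel)
  if (any(issues$issue == "orphan_sample"))
    abort_join(paste0("sample id(s) on plates but not in the sample sheet: ",
                      paste(unique(issues$sample_id[issues$issue == "orphan_sample"]),
                            collapse = ", ")))
  if (any(issues$issue == "unknown_substrate"))
    abort_lookup(paste0("substrate id(s) not in the panel: ",
                        paste(unique(issues$substrate_id[issues$issue == "unknown_substrate"]),
                              collapse = ", ")))
  if (any(issues$issue == "missing_intrinsic"))
    abort_pairing(paste0("digestion wells without an intrinsic control: sample(s) ",
                         paste(unique(issues$sample_id[issues$issue == "missing_intrinsic"]),
                               collapse = ", ")))

  ref <- reference_value(runs, control$reference_plate)
  factors <- do.call(rbind, lapply(runs, plate_normalization_factor, reference_value = ref))
  rownames(factors) <- NULL
  normalized <- Map(normalize_plate, runs, factors$factor)

  baselines <- intrinsic_baselines(normalized)
  qc <- flag_high_background(baselines, normalized, control$qc)

  resid_rows <- list()
  well_rows <- lapply(normalized, function(run) {
    intr <- plate_traces(run, "intrinsic")
    intr_by_sample <- vapply(intr, function(tr) tr$sample_id, character(1))
    dig <- plate_traces(run, "digestion")
    if (!length(dig)) return(NULL)
    rows <- lapply(dig, function(tr) {
      corrected <- subtract_intrinsic(tr, intr[[match(tr$sample_id, intr_by_sample)]])
      win <- detect_linear_phase(corrected, control$window)
      fit <- fit_slope(corrected, win)
      ok <- !is.na(corrected$rfu) &
        corrected$time_min >= win$t_start - 1e-9 &
        corrected$time_min <= win$t_end + 1e-9
      line <- ols_line(corrected$time_min[ok], corrected$rfu[ok])
      resid_rows[[paste0(run$plate_id, "/", tr$well_id)]] <<- data.frame(
        plate_id = run$plate_id, well_id = tr$well_id,
        time_min = corrected$time_min[ok], residual = line$residuals,
        stringsAsFactors = FALSE)
      data.frame(plate_id = run$plate_id, well_id = tr$well_id,
                 sample_id = tr$sample_id, substrate_id = tr$substrate_id,
                 ph = tr$ph, replicate = tr$replicate,
                 rate_rfu_per_min = fit$rate_rfu_per_min, stderr = fit$stderr,
                 r_squared = fit$r_squared,
                 window_start = win$t_start, window_end = win$t_end,
                 window_points = win$n_points, low_activity = win$low_activity,
                 normalization_factor = run$meta$normalization_factor,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  well_fits <- do.call(rbind, well_rows)
  rownames(well_fits) <- NULL

  records <- aggregate_well_fits(well_fits, sheet, qc)
  mat <- build_activity_matrix(records, sheet, drop_excluded = control$drop_excluded)

  structure(
    list(records = records, well_fits = well_fits, qc = qc,
         norm_factors = factors, reference_value = ref, matrix = mat,
         residual_table = { r <- do.call(rbind, resid_rows); rownames(r) <- NULL; r },
         issues = issues, sheet = sheet, panel = panel, control = control,
         call = match.call()),
    class = "activity_fit")
}

# Replicate aggregation of per-well slopes into ActivityRecords.
aggregate_well_fits <- function(well_fits, sheet, qc) {
  key <- paste(well_fits$sample_id, well_fits$substrate_id, well_fits$ph, sep = "\r")
  parts <- split(well_fits, factor(key, levels = unique(key)))
  rows <- lapply(parts, function(p) {
    agg <- aggregate_replicates(p$rate_rfu_per_min)
    data.frame(sample_id = p$sample_id[1L],
               cohort = sheet$cohort[match(p$sample_id[1L], sheet$sample_id)],
               substrate_id = p$substrate_id[1L], ph = p$ph[1L],
               rate_rfu_per_min = agg$mean, rate_sd = agg$sd, n_replicates = agg$n,
               low_activity = all(p$low_activity),
               qc_excluded = isTRUE(qc$excluded[match(p$sample_id[1L], qc$sample_id)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.activity_fit <- function(x, ...) {
  cat("Protease activity fit\n")
  cat(sprintf("  %d plates, %d digestion wells, %d samples (%d QC-excluded)\n",
              nrow(x$norm_factors), nrow(x$well_fits),
              nrow(x$qc), sum(x$qc$excluded)))
  cat(sprintf("  %d activity records over %d substrates x %d pH levels\n",
              nrow(x$records), length(unique(x$records$substrate_id)),
              length(unique(x$records$ph))))
  cat(sprintf("  normalization reference value: %.3g RFU\n", x$reference_value))
  invisible(x)
}

#' @export
summary.activity_fit <- function(object, ...) {
  rec <- object$records[!object$records$qc_excluded, , drop = FALSE]
  by_cohort <- if (nrow(rec)) {
    agg <- stats::aggregate(rate_rfu_per_min ~ cohort + substrate_id,
                            data = rec, FUN = mean)
    do.call(rbind, lapply(split(agg, agg$cohort), function(d) {
      d <- d[order(-d$rate_rfu_per_min), , drop = FALSE][1L, , drop = FALSE]
      names(d)[names(d) == "substrate_id"] <- "top_substrate"
      names(d)[names(d) == "rate_rfu_per_min"] <- "top_mean_rate"
      d
    }))
  } else NULL
  structure(list(n_samples = nrow(object$qc), n_excluded = sum(object$qc$excluded),
                 exclusion_reasons = table(object$qc$reason[object$qc$excluded]),
                 cohort_sizes = table(object$sheet$cohort),
                 reference_value = object$reference_value,
                 factor_range = range(object$norm_factors$factor),
                 top_by_cohort = by_cohort,
                 low_activity_share = mean(object$records$low_activity)),
            class = "summary.activity_fit")
}

#' @export
print.summary.activity_fit <- function(x, ...) {
  cat("Protease activity fit -- summary\n")
  cat(sprintf("  samples: %d (%s)\n", x$n_samples,
              paste(sprintf("%s=%d", names(x$cohort_sizes), as.integer(x$cohort_sizes)),
                    collapse = ", ")))
  cat(sprintf("  QC-excluded: %d%s\n", x$n_excluded,
              if (x$n_excluded)
                paste0(" (", paste(sprintf("%s: %d", names(x$exclusion_reasons),
                                           as.integer(x$exclusion_reasons)),
                                   collapse = ", "), ")")
              else ""))
  cat(sprintf("  normalization factors in [%.3f, %.3f] (reference %.3g RFU)\n",
              x$factor_range[1L], x$factor_range[2L], x$reference_value))
  cat(sprintf("  low-activity records: %.1f%%\n", 100 * x$low_activity_share))
  if (!is.null(x$top_by_cohort)) {
    cat("  most active substrate per cohort (mean RFU/min over pH):\n")
    for (i in seq_len(nrow(x$top_by_cohort)))
      cat(sprintf("    %-4s %-16s %8.1f\n", x$top_by_cohort$cohort[i],
                  x$top_by_cohort$top_substrate[i], x$top_by_cohort$top_mean_rate[i]))
  }
  invisible(x)
}

#' @export
#' @describeIn fit_activity The samples x (substrate, pH) activity matrix.
coef.activity_fit <- function(object, ...) object$matrix

#' @export
#' @describeIn fit_activity Per-read OLS residuals of every fitted window
#'   (long data frame: `plate_id`, `well_id`, `time_min`, `residual`).
residuals.activity_fit <- function(object, ...) object$residual_table

#' @export
#' @describeIn fit_activity Heatmap of the cohort mean profile (substrates x
#'   (cohort, pH)); display values are clipped to `clip_range` without
#'   altering stored rates.
plot.activity_fit <- function(x, clip_range = c(0, 600), ...) {
  prof <- cohort_mean_profile(x$matrix)
  cols <- unique(prof[, c("cohort", "ph")])
  cols <- cols[order(cols$ph, cols$cohort), , drop = FALSE]
  subs <- unique(prof$substrate_id)
  z <- matrix(NA_real_, nrow = length(subs), ncol = nrow(cols),
              dimnames = list(subs, paste0(cols$cohort, "@", cols$ph)))
  for (i in seq_len(nrow(prof))) {
    z[prof$substrate_id[i], paste0(prof$cohort[i], "@", prof$ph[i])] <- prof$mean_rate[i]
  }
  zc <- pmin(pmax(z, clip_range[1L]), clip_range[2L])
  op <- graphics::par(mar = c(6, 9, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(x = seq_len(ncol(zc)), y = seq_len(nrow(zc)), z = t(zc),
                  col = pal, zlim = clip_range, axes = FALSE,
                  xlab = "", ylab = "", main = "Cohort mean protease activity (RFU/min)")
  graphics::axis(1, at = seq_len(ncol(zc)), labels = colnames(zc), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(zc)), labels = rownames(zc), las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(z)
}
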