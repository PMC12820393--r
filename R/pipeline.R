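# End-to-end orchestration: simulate/read -> QC -> kinetics -> profiling ->
# stats, emitting a reproducible report bundle.

#' Configure an end-to-end pipeline run
#'
#' Exactly one input source must be given: a [sim_config()] (the run
#' simulates its dataset) or `input`, a list of file paths
#' (`kinetics`, `sheet`, and optionally `panel`) produced by/for
#' [read_kinetic_table()] and [read_sample_sheet()].
#'
#' @param simulation A [sim_config()], or `NULL`.
#' @param input List of input paths, or `NULL`.
#' @param qc A [qc_policy()].
#' @param window [linear_phase_options()].
#' @param reference_plate Designated reference plate id (`NULL` = first).
#' @param drop_excluded Drop QC-excluded samples from analysis tables.
#' @param contribution_scope `"per_ph"` or `"across_ph"` for
#'   [normalized_contributions()].
#' @param comparisons List of cohort pairs (length-2 character vectors) for
#'   the per-condition t tests; `NULL` compares all cohort pairs.
#' @param var_equal Pooled-variance t tests (default) or Welch.
#' @param adjust_p Add Benjamini-Hochberg adjusted p values to the stats
#'   report.
#' @param roc_comparisons List of ROC requests, each a list with
#'   `cohort_a` (positive class), `cohort_b`, `substrate_id`, `ph`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Optional integer overriding the simulation config's seed.
#' @param verbose Emit progress messages to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, input = NULL,
                       qc = qc_policy(), window = linear_phase_options(),
                       reference_plate = NULL, drop_excluded = TRUE,
                       contribution_scope = c("per_ph", "across_ph"),
                       comparisons = NULL, var_equal = TRUE, adjust_p = FALSE,
                       roc_comparisons = list(),
                       out_dir = tempfile("ppa_run_"), seed = NULL,
                       verbose = FALSE) {
  contribution_scope <- match.arg(contribution_scope)
  if (is.null(simulation) == is.null(input))
    abort_config("exactly one of 'simulation' or 'input' must be given")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    abort_config("'simulation' must be a sim_config object")
  if (!is.null(input)) {
    if (!is.list(input) || !all(c("kinetics", "sheet") %in% names(input)))
      abort_config("'input' must be a list with elements 'kinetics' and 'sheet'")
  }
  for (rc in roc_comparisons) {
    if (!is.list(rc) || !all(c("cohort_a", "cohort_b", "substrate_id", "ph") %in% names(rc)))
      abort_config("each ROC comparison needs cohort_a, cohort_b, substrate_id, ph")
  }
  structure(list(simulation = simulation, input = input, qc = qc,
                 window = window, reference_plate = reference_plate,
                 drop_excluded = isTRUE(drop_excluded),
                 contribution_scope = contribution_scope,
                 comparisons = comparisons, var_equal = isTRUE(var_equal),
                 adjust_p = isTRUE(adjust_p),
                 roc_comparisons = roc_comparisons,
                 out_dir = out_dir, seed = seed, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Maps a flat configuration file onto [run_config()] (and, for simulated
#' runs, [sim_config()]). Recognized top-level keys: `simulation` (a mapping
#' of [sim_config()] arguments except `panel` and `effect_matrix`, which use
#' the built-in defaults), `input` (`kinetics`, `sheet`, `panel` paths),
#' `qc` (`type`, `k`, `threshold_rfu`), `window` (arguments of
#' [linear_phase_options()]), and the remaining scalar [run_config()]
#' arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$simulation)) {
    args <- raw$simulation
    if (!is.null(args$cohorts)) args$cohorts <- unlist(args$cohorts)
    sim <- do.call(sim_config, args)
  }
  qc <- if (is.null(raw$qc)) qc_policy() else do.call(qc_policy, raw$qc)
  window <- if (is.null(raw$window)) linear_phase_options()
            else do.call(linear_phase_options, raw$window)
  roc <- raw$roc_comparisons %||% list()
  if (is.data.frame(roc)) roc <- lapply(seq_len(nrow(roc)), function(i) as.list(roc[i, ]))
  run_config(simulation = sim, input = raw$input, qc = qc, window = window,
             reference_plate = raw$reference_plate,
             drop_excluded = raw$drop_excluded %||% TRUE,
             contribution_scope = raw$contribution_scope %||% "per_ph",
             comparisons = raw$comparisons,
             var_equal = raw$var_equal %||% TRUE,
             adjust_p = raw$adjust_p %||% FALSE,
             roc_comparisons = roc,
             out_dir = raw$out_dir %||% tempfile("ppa_run_"),
             seed = raw$seed, verbose = raw$verbose %||% FALSE)
}

#' Run the full profiling pipeline and write a report bundle
#'
#' Composes the whole analysis: obtain data (simulate or read), fit activity
#' rates ([fit_activity()]), build the cohort mean profile and normalized
#' substrate/class contributions, run per-condition cohort comparisons and
#' any requested ROC analyses, and write a deterministic bundle of CSV/JSON
#' outputs plus a machine-readable run manifest recording every policy and
#' threshold that affected the numbers. Identical configurations (including
#' seed) produce byte-identical bundles. A requested comparison whose cohort
#' has no usable samples is skipped with a logged warning, not an error.
#'
#' @param config A [run_config()] or a path accepted by [read_run_config()].
#' @return A `ppa_bundle`: `dir`, `files` (named paths of the outputs),
#'   `fit`, `profile`, `contributions`, `stats`, `roc`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (config$verbose) message(sprintf(...))
  warnings_seen <- character(0)
  note <- function(msg) {
    warnings_seen <<- c(warnings_seen, msg)
    warning(msg, call. = FALSE)
  }

  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    if (!is.null(config$seed)) {
      sim_cfg$seed <- as.integer(config$seed)
    }
    log_msg("simulating study (seed %d)", sim_cfg$seed)
    sim <- simulate_study(sim_cfg)
    runs <- sim$plates; sheet <- sim$sheet; panel <- sim_cfg$panel
  } else {
    log_msg("reading %s", config$input$kinetics)
    runs <- read_kinetic_table(config$input$kinetics)
    sheet <- read_sample_sheet(config$input$sheet)
    panel <- load_substrate_panel(config$input$panel)
  }

  # Validate ROC requests against the loaded cohorts/panel before computing.
  for (rc in config$roc_comparisons) {
    if (!all(c(rc$cohort_a, rc$cohort_b) %in% sheet$cohort))
      abort_config(sprintf("ROC comparison references unknown cohort(s): %s vs %s",
                           rc$cohort_a, rc$cohort_b))
    if (!rc$substrate_id %in% panel$substrate_id)
      abort_config(sprintf("ROC comparison references unknown substrate %s", rc$substrate_id))
  }

  control <- activity_control(qc = config$qc, window = config$window,
                              reference_plate = config$reference_plate,
                              drop_excluded = config$drop_excluded)
  log_msg("fitting activity rates")
  fit <- fit_activity(runs, sheet, panel, control)

  profile <- suppressWarnings(cohort_mean_profile(fit$matrix))
  contributions <- rbind(
    normalized_contributions(profile, panel, "substrate", config$contribution_scope),
    normalized_contributions(profile, panel, "class", config$contribution_scope))

  stats_tab <- cohort_comparisons(fit, config$comparisons, config$var_equal,
                                  config$adjust_p, note)
  roc_out <- run_roc_comparisons(fit, config$roc_comparisons, note)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(qc_report = "qc_report.csv", activity_table = "activity_table.csv",
             cohort_profile = "cohort_profile.csv", contributions = "contributions.csv",
             stats_report = "stats_report.csv", roc_curves = "roc_curves.csv",
             summary = "summary.json", manifest = "manifest.json")
  files <- setNames(file.path(config$out_dir, files), names(files))

  utils::write.csv(fit$qc, files[["qc_report"]], row.names = FALSE, na = "")
  activity_table <- merge(fit$records,
                          fit$well_fits[!duplicated(paste(fit$well_fits$sample_id,
                                                          fit$well_fits$substrate_id,
                                                          fit$well_fits$ph)),
                                        c("sample_id", "substrate_id", "ph",
                                          "window_start", "window_end",
                                          "normalization_factor")],
                          by = c("sample_id", "substrate_id", "ph"), sort = TRUE)
  utils::write.csv(activity_table, files[["activity_table"]], row.names = FALSE, na = "")
  utils::write.csv(profile, files[["cohort_profile"]], row.names = FALSE, na = "")
  utils::write.csv(contributions, files[["contributions"]], row.names = FALSE, na = "")
  utils::write.csv(stats_tab, files[["stats_report"]], row.names = FALSE, na = "")
  utils::write.csv(roc_out$curves, files[["roc_curves"]], row.names = FALSE, na = "")

  summary_json <- list(
    n_samples = nrow(fit$qc), n_excluded = sum(fit$qc$excluded),
    reference_value = fit$reference_value,
    aucs = roc_out$aucs)
  jsonlite::write_json(summary_json, files[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    package = "protrace",
    version = as.character(utils::packageVersion("protrace")),
    seed = if (!is.null(config$simulation)) sim_cfg$seed else config$seed,
    config_hash = config_hash(config),
    qc_policy = config$qc[c("type", "k", "threshold_rfu")],
    qc_threshold_used = fit$qc$threshold_used[1L],
    window_options = unclass(config$window),
    reference_plate = config$reference_plate %||% "first-in-order",
    reference_value = fit$reference_value,
    contribution_scope = config$contribution_scope,
    var_equal = config$var_equal, adjust_p = config$adjust_p,
    drop_excluded = config$drop_excluded,
    n_layout_issues = nrow(fit$issues),
    warnings = warnings_seen)
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(dir = config$out_dir, files = files, fit = fit,
                 profile = profile, contributions = contributions,
                 stats = stats_tab, roc = roc_out, manifest = manifest),
            class = "ppa_bundle")
}

# Serialize the run configuration canonically and hash it. The output
# directory and verbosity are presentation details, not analysis inputs, so
# they stay out of the hash (identical analyses hash identically wherever
# they are written).
config_hash <- function(config) {
  slim <- config
  slim$out_dir <- NULL
  slim$verbose <- NULL
  slim$simulation <- if (!is.null(config$simulation)) {
    s <- config$simulation
    list(cohorts = as.list(s$cohorts), ph_levels = s$ph_levels,
         effect_matrix = s$effect_matrix, cv_log = s$cv_log,
         tau = if (is.data.frame(s$depletion_tau_min)) s$depletion_tau_min
               else unname(s$depletion_tau_min),
         noise_sd_rfu = s$noise_sd_rfu,
         background = c(s$background_mean_rfu, s$background_sd_rfu),
         high_background = c(s$high_background_fraction, s$high_background_multiplier),
         plate_gain_sd = s$plate_gain_sd, replicates = s$replicates,
         timepoints = s$timepoints_min, seed = s$seed)
  }
  slim$qc <- unclass(slim$qc); slim$window <- unclass(slim$window)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(slim[sort(names(slim))], tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

# Per-(substrate, pH) unpaired cohort comparisons.
cohort_comparisons <- function(fit, comparisons, var_equal, adjust_p, note) {
  mat <- fit$matrix
  cohorts <- attr(mat, "cohort")
  if (is.null(comparisons)) {
    labs <- sort(unique(cohorts))
    comparisons <- if (length(labs) < 2L) list()
                   else utils::combn(labs, 2L, simplify = FALSE)
  }
  cond <- matrix_conditions(mat)
  rows <- list()
  for (cmp in comparisons) {
    a_lab <- cmp[[1L]]; b_lab <- cmp[[2L]]
    for (j in seq_len(ncol(mat))) {
      a <- mat[cohorts == a_lab, j]; a <- a[!is.na(a)]
      b <- mat[cohorts == b_lab, j]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) {
        note(sprintf("comparison %s vs %s skipped for %s: fewer than 2 usable samples",
                     a_lab, b_lab, colnames(mat)[j]))
        next
      }
      tt <- unpaired_t_test(a, b, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0(a_lab, "_vs_", b_lab),
        substrate_id = cond$substrate_id[j], ph = cond$ph[j],
        test_kind = tt$kind, n_a = tt$n_a, n_b = tt$n_b,
        statistic = tt$statistic, df = tt$df, p = tt$p_value,
        ci_low = tt$ci95[1L], ci_high = tt$ci95[2L],
        mean_diff = tt$estimate, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(comparison = character(0), substrate_id = character(0),
                      ph = numeric(0), test_kind = character(0),
                      n_a = integer(0), n_b = integer(0), statistic = numeric(0),
                      df = numeric(0), p = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), mean_diff = numeric(0)))
  out <- do.call(rbind, rows)
  if (adjust_p) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

run_roc_comparisons <- function(fit, roc_comparisons, note) {
  mat <- fit$matrix
  cohorts <- attr(mat, "cohort")
  curves <- list(); aucs <- list()
  for (rc in roc_comparisons) {
    col <- paste0(rc$substrate_id, "@", rc$ph)
    id <- sprintf("%s_vs_%s_%s_pH%s", rc$cohort_a, rc$cohort_b, rc$substrate_id, rc$ph)
    if (!col %in% colnames(mat)) {
      note(sprintf("ROC %s skipped: no activity column %s", id, col))
      next
    }
    keep <- cohorts %in% c(rc$cohort_a, rc$cohort_b) & !is.na(mat[, col])
    if (sum(cohorts[keep] == rc$cohort_a) < 1L || sum(cohorts[keep] == rc$cohort_b) < 1L) {
      note(sprintf("ROC %s skipped: a cohort has no usable samples", id))
      next
    }
    r <- roc_curve_auc(mat[keep, col], cohorts[keep], rc$cohort_a)
    aucs[[id]] <- r$auc
    curves[[id]] <- cbind(comparison = id, r$curve, stringsAsFactors = FALSE)
  }
  curve_df <- if (length(curves)) do.call(rbind, curves)
              else data.frame(comparison = character(0), threshold = numeric(0),
                              fpr = numeric(0), tpr = numeric(0))
  rownames(curve_df) <- NULL
  list(curves = curve_df, aucs = aucs)
}

#' Render a human-readable summary of a pipeline bundle
#'
#' @param bundle A `ppa_bundle` from [run_pipeline()].
#' @return Character vector of report lines (also printed), deterministic
#'   for identical bundles.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "ppa_bundle"))
  for (member in c("fit", "profile", "contributions", "stats", "roc", "manifest"))
    if (is.null(bundle[[member]]))
      stop_protrace(sprintf("bundle is missing member '%s'", member), "report_error")
  s <- summary(bundle$fit)
  lines <- c(
    "Protease activity profiling report",
    "==================================",
    sprintf("Samples: %d across %d cohorts (%s)",
            s$n_samples, length(s$cohort_sizes),
            paste(sprintf("%s=%d", names(s$cohort_sizes), as.integer(s$cohort_sizes)),
                  collapse = ", ")),
    sprintf("%d samples excluded by QC (threshold %.4g RFU, policy %s)",
            s$n_excluded, bundle$manifest$qc_threshold_used,
            bundle$manifest$qc_policy$type),
    sprintf("Normalization: reference value %.4g RFU; factors in [%.3f, %.3f]",
            s$reference_value, s$factor_range[1L], s$factor_range[2L]))
  if (!is.null(s$top_by_cohort)) {
    lines <- c(lines, "Most active substrate per cohort (mean RFU/min):",
               sprintf("  %-4s %-16s %8.1f", s$top_by_cohort$cohort,
                       s$top_by_cohort$top_substrate, s$top_by_cohort$top_mean_rate))
  }
  cls <- bundle$contributions[bundle$contributions$level == "class" &
                                bundle$contributions$unit == "cysteine", , drop = FALSE]
  if (nrow(cls)) {
    lines <- c(lines, "Cysteine-class share of total activity:",
               sprintf("  %-4s pH %-4s %5.1f%%", cls$cohort,
                       ifelse(is.na(cls$ph), "all", cls$ph), 100 * cls$fraction))
  }
  if (nrow(bundle$stats)) {
    top <- bundle$stats[order(bundle$stats$p), , drop = FALSE][
      seq_len(min(5L, nrow(bundle$stats))), , drop = FALSE]
    lines <- c(lines, "Smallest-p cohort comparisons:",
               sprintf("  %-12s %-16s pH %-4s p = %.3g", top$comparison,
                       top$substrate_id, top$ph, top$p))
  }
  if (length(bundle$roc$aucs)) {
    lines <- c(lines, "ROC discrimination:",
               sprintf("  %-30s AUC = %.3f", names(bundle$roc$aucs),
                       unlist(bundle$roc$aucs)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.ppa_bundle <- function(x, ...) {
  cat(sprintf("<ppa_bundle> %d output files in %s\n", length(x$files), x$dir))
  invisible(x)
}
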