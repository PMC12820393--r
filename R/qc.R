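# Intrinsic-fluorescence quality control.
#
# Stool extracts can carry substrate-independent fluorescence (soluble
# fluorophores such as incompletely absorbed mesalazine). Each extract is
# measured without substrate (role = "intrinsic"); that trace quantifies the
# sample's baseline, is subtracted from the sample's digestion curves before
# slope estimation, and -- where excessive -- excludes the sample from
# enzymatic analysis.

#' Summarize an intrinsic-fluorescence well
#'
#' @param trace A [kinetic_trace()] with `role == "intrinsic"`.
#' @return A one-row data frame (`sample_id`, `plate_id`, `baseline_rfu`,
#'   `baseline_sd_rfu`, `n_reads`, `incomplete`): the arithmetic mean and
#'   sample SD of the well's reads.
#' @export
intrinsic_baseline <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (trace$role != "intrinsic")
    abort_input(sprintf("trace %s/%s has role '%s'; an intrinsic well is required",
                        trace$plate_id, trace$well_id, trace$role))
  rfu <- trace$rfu[!is.na(trace$rfu)]
  data.frame(sample_id = trace$sample_id, plate_id = trace$plate_id,
             baseline_rfu = mean(rfu), baseline_sd_rfu = stats::sd(rfu),
             n_reads = length(rfu), incomplete = trace$incomplete,
             stringsAsFactors = FALSE)
}

#' Intrinsic baselines for every sample across plates
#'
#' Applies [intrinsic_baseline()] to every intrinsic well of every plate.
#'
#' @param runs List of [plate_run()] objects.
#' @return Data frame with one row per intrinsic well.
#' @export
intrinsic_baselines <- function(runs) {
  if (inherits(runs, "plate_run")) runs <- list(runs)
  rows <- unlist(lapply(runs, function(run)
    lapply(plate_traces(run, "intrinsic"), intrinsic_baseline)), recursive = FALSE)
  if (!length(rows))
    return(data.frame(sample_id = character(0), plate_id = character(0),
                      baseline_rfu = numeric(0), baseline_sd_rfu = numeric(0),
                      n_reads = integer(0), incomplete = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclusion policy for high intrinsic fluorescence
#'
#' Two policies decide which extracts show "excessively high" intrinsic
#' fluorescence: `absolute` excludes samples whose mean intrinsic baseline
#' exceeds a fixed RFU threshold; `adaptive` references the plate background,
#' excluding samples above `mean(empty-well RFU) + k * SD(empty-well RFU)`
#' pooled over all plates (default `k = 10`).
#'
#' @param type `"adaptive"` or `"absolute"`.
#' @param k Multiplier for the adaptive policy.
#' @param threshold_rfu Fixed threshold for the absolute policy.
#' @return A `qc_policy` object.
#' @export
qc_policy <- function(type = c("adaptive", "absolute"), k = 10, threshold_rfu = NULL) {
  type <- match.arg(type)
  if (type == "absolute" && !is_number(threshold_rfu))
    abort_config("absolute policy needs a numeric 'threshold_rfu'")
  if (type == "adaptive" && (!is_number(k) || k <= 0))
    abort_config("adaptive policy needs k > 0")
  structure(list(type = type, k = k, threshold_rfu = threshold_rfu),
            class = "qc_policy")
}

#' Flag samples for exclusion on intrinsic fluorescence
#'
#' Applies a [qc_policy()] to per-sample intrinsic baselines. A sample is
#' excluded if any of its intrinsic wells exceeds the threshold (reason
#' `high_intrinsic_fluorescence`) or if its intrinsic trace is missing reads
#' (reason `incomplete_trace`). The threshold actually used is recorded on
#' every flag so reports are self-describing.
#'
#' @param baselines Data frame from [intrinsic_baselines()].
#' @param runs List of [plate_run()] objects (needed by the adaptive policy
#'   for empty-well reads; may be `NULL` for the absolute policy).
#' @param policy A [qc_policy()].
#' @return Data frame with one row per sample: `sample_id`, `excluded`,
#'   `reason` (`high_intrinsic_fluorescence`, `incomplete_trace`, or `none`),
#'   `baseline_rfu` (max over the sample's intrinsic wells), `threshold_used`.
#' @export
flag_high_background <- function(baselines, runs = NULL, policy = qc_policy()) {
  stopifnot(inherits(policy, "qc_policy"))
  threshold <- if (policy$type == "absolute") {
    policy$threshold_rfu
  } else {
    if (is.null(runs)) abort_config("adaptive policy requires plate runs for empty wells")
    if (inherits(runs, "plate_run")) runs <- list(runs)
    empty <- unlist(lapply(runs, empty_well_reads), use.names = FALSE)
    empty <- empty[!is.na(empty)]
    if (!length(empty))
      abort_config("adaptive policy requires at least one empty well across plates")
    mean(empty) + policy$k * stats::sd(empty)
  }
  samples <- unique(baselines$sample_id)
  rows <- lapply(samples, function(s) {
    b <- baselines[baselines$sample_id == s, , drop = FALSE]
    peak <- max(b$baseline_rfu)
    reason <- if (peak > threshold) "high_intrinsic_fluorescence"
              else if (any(b$incomplete)) "incomplete_trace"
              else "none"
    data.frame(sample_id = s, excluded = reason != "none", reason = reason,
               baseline_rfu = peak, threshold_used = threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subtract a sample's intrinsic trace from a digestion curve
#'
#' Because autofluorescence varies between extracts, the intrinsic
#' (extract-only) trace of each sample is subtracted read-by-read from its
#' digestion curves before slope estimation. The corrected trace may contain
#' negative values under noise; they are retained (slope fitting is
#' offset-invariant).
#'
#' @param digestion A `digestion`-role [kinetic_trace()].
#' @param intrinsic The matching `intrinsic`-role trace of the same sample,
#'   on an identical timepoint grid.
#' @return The corrected digestion trace; `meta$corrected_by` records the
#'   intrinsic well used.
#' @export
subtract_intrinsic <- function(digestion, intrinsic) {
  stopifnot(inherits(digestion, "kinetic_trace"), inherits(intrinsic, "kinetic_trace"))
  if (intrinsic$role != "intrinsic")
    abort_input("'intrinsic' must be an intrinsic-role trace")
  if (is.na(digestion$sample_id) || digestion$sample_id != intrinsic$sample_id)
    abort_pairing(sprintf("sample mismatch: digestion %s vs intrinsic %s",
                          digestion$sample_id, intrinsic$sample_id))
  if (length(digestion$time_min) != length(intrinsic$time_min) ||
      any(digestion$time_min != intrinsic$time_min))
    abort_alignment("digestion and intrinsic traces are on different timepoint grids")
  out <- digestion
  out$rfu <- digestion$rfu - intrinsic$rfu
  out$incomplete <- anyNA(out$rfu)
  out$meta$corrected_by <- paste0(intrinsic$plate_id, "/", intrinsic$well_id)
  out
}
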