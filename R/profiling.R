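# Sample x (substrate, pH) assembly and cohort-level signatures.

#' Assemble the samples x (substrate, pH) activity matrix
#'
#' @param records Activity records (e.g. `fit_activity(...)$records`): one row
#'   per (sample, substrate, pH) with `rate_rfu_per_min` and `qc_excluded`.
#' @param sheet Sample sheet; every record's sample must appear in it.
#' @param drop_excluded Drop QC-excluded samples entirely (`TRUE`) or keep
#'   them as all-missing rows (`FALSE`).
#' @return An `activity_matrix`: numeric matrix, rows = samples, columns =
#'   `"substrate@pH"` pairs, with `cohort` and `phase` attributes aligned to
#'   the rows. Missing cells are `NA`.
#' @export
build_activity_matrix <- function(records, sheet, drop_excluded = TRUE) {
  sheet <- validate_sample_sheet(sheet)
  missing_samples <- setdiff(records$sample_id, sheet$sample_id)
  if (length(missing_samples))
    abort_join(paste0("record sample(s) not in the sample sheet: ",
                      paste(missing_samples, collapse = ", ")))
  key <- paste(records$sample_id, records$substrate_id, records$ph, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1L, ]
    abort_integrity(sprintf("duplicate activity record for (%s, %s, pH %s)",
                            d$sample_id, d$substrate_id, d$ph))
  }
  excluded <- unique(records$sample_id[records$qc_excluded])
  samples <- sheet$sample_id[sheet$sample_id %in% records$sample_id]
  if (drop_excluded) samples <- setdiff(samples, excluded)
  cond <- unique(records[, c("substrate_id", "ph")])
  cond <- cond[order(cond$substrate_id, cond$ph), , drop = FALSE]
  cols <- paste0(cond$substrate_id, "@", cond$ph)
  mat <- matrix(NA_real_, nrow = length(samples), ncol = length(cols),
                dimnames = list(samples, cols))
  usable <- records[!records$qc_excluded & records$sample_id %in% samples, , drop = FALSE]
  mat[cbind(match(usable$sample_id, samples),
            match(paste0(usable$substrate_id, "@", usable$ph), cols))] <-
    usable$rate_rfu_per_min
  structure(mat,
            cohort = sheet$cohort[match(samples, sheet$sample_id)],
            phase = sheet$phase[match(samples, sheet$sample_id)],
            class = c("activity_matrix", "matrix", "array"))
}

# (substrate, ph) pairs encoded in an activity matrix's column names.
matrix_conditions <- function(mat) {
  parts <- strsplit(colnames(mat), "@", fixed = TRUE)
  data.frame(substrate_id = vapply(parts, `[`, character(1), 1L),
             ph = as.numeric(vapply(parts, `[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Cohort mean activity profile
#'
#' Arithmetic mean rate per (cohort, substrate, pH) over the non-missing,
#' non-excluded samples of the activity matrix -- the table behind
#' cohort-level heatmaps. Display clipping, where used, applies to rendering
#' only; stored means are never clipped.
#'
#' @param matrix An `activity_matrix` from [build_activity_matrix()] (or
#'   [coef()] on an `activity_fit`).
#' @param clip_range Optional display clip range recorded on the result.
#' @return A `cohort_profile` data frame: `cohort`, `substrate_id`, `ph`,
#'   `mean_rate`, `n`. Cohorts with no usable sample for a cell get `NA` with
#'   a warning, not an error.
#' @export
cohort_mean_profile <- function(matrix, clip_range = NULL) {
  stopifnot(inherits(matrix, "activity_matrix"))
  cohorts <- attr(matrix, "cohort")
  cond <- matrix_conditions(matrix)
  rows <- list()
  for (co in unique(cohorts)) {
    sub <- matrix[cohorts == co, , drop = FALSE]
    n_ok <- colSums(!is.na(sub))
    m <- suppressWarnings(colMeans(sub, na.rm = TRUE))
    m[n_ok == 0L] <- NA_real_
    if (any(n_ok == 0L))
      warning(sprintf("cohort %s has no usable sample for %d cell(s); means set to NA",
                      co, sum(n_ok == 0L)), call. = FALSE)
    rows[[co]] <- data.frame(cohort = co, substrate_id = cond$substrate_id,
                             ph = cond$ph, mean_rate = unname(m),
                             n = unname(n_ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "clip_range") <- clip_range
  class(out) <- c("cohort_profile", "data.frame")
  out
}

#' Normalized substrate- or class-level activity contributions
#'
#' Converts a cohort mean profile into fractions of total activity: for each
#' cohort (within each pH with `scope = "per_ph"`, or pooling all pH with
#' `scope = "across_ph"`), mean rates are clamped at zero (a share of total
#' activity cannot be negative; raw means stay unclamped in the profile) and
#' divided by their sum. At `level = "class"` substrate rates are first
#' summed within the serine and cysteine protease classes, so class fractions
#' equal the sum of their member substrates' fractions by construction.
#'
#' @param profile A [cohort_mean_profile()].
#' @param panel Substrate panel supplying class assignments.
#' @param level `"substrate"` or `"class"`.
#' @param scope `"per_ph"` (default) or `"across_ph"`.
#' @return A `contribution_table` data frame: `cohort`, `ph` (`NA` for
#'   `across_ph`), `level`, `unit` (substrate id or protease class),
#'   `fraction`, `denominator` (the clamped-rate total in RFU/min). When a
#'   block's denominator is zero all its fractions are `NA`.
#' @export
normalized_contributions <- function(profile, panel = load_substrate_panel(),
                                     level = c("substrate", "class"),
                                     scope = c("per_ph", "across_ph")) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  stopifnot(inherits(profile, "cohort_profile"))
  panel <- validate_substrate_panel(as.data.frame(panel))
  unknown <- setdiff(unique(profile$substrate_id), panel$substrate_id)
  if (length(unknown))
    abort_lookup(paste0("substrate(s) absent from panel: ",
                        paste(unknown, collapse = ", ")))
  df <- profile
  df$clamped <- pmax(df$mean_rate, 0)
  df$clamped[is.na(df$mean_rate)] <- NA_real_
  df$unit <- if (level == "substrate") df$substrate_id
             else panel$protease_class[match(df$substrate_id, panel$substrate_id)]
  df$block <- if (scope == "per_ph") paste(df$cohort, df$ph, sep = "\r") else df$cohort
  rows <- lapply(split(df, factor(df$block, levels = unique(df$block))), function(b) {
    per_unit <- tapply(b$clamped, b$unit, function(v) sum(v, na.rm = TRUE))
    units <- if (level == "class") intersect(substrate_classes, names(per_unit))
             else sort(names(per_unit))
    per_unit <- per_unit[units]
    denom <- sum(per_unit)
    data.frame(cohort = b$cohort[1L],
               ph = if (scope == "per_ph") b$ph[1L] else NA_real_,
               level = level, unit = units,
               fraction = if (denom > 0) unname(per_unit) / denom
                          else rep(NA_real_, length(units)),
               denominator = denom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contribution_table", "data.frame")
  out
}
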