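# Reading and writing the long-format kinetics interchange tables.
#
# Canonical interchange format: a tidy CSV with one row per (well, timepoint)
# and header plate_id, well_id, sample_id, substrate_id, ph, replicate, role,
# time_min, rfu. Vendor exports (wide Tecan grids etc.) are expected to be
# pre-converted to this layout.

kinetic_table_columns <- c("plate_id", "well_id", "sample_id", "substrate_id",
                           "ph", "replicate", "role", "time_min", "rfu")

#' Read a long-format kinetics table into plate runs
#'
#' Parses the tidy per-read CSV export into a list of [plate_run()] objects,
#' grouping rows by plate and well and validating the structural invariants
#' (shared timepoint grid within a plate, unique wells, role/identity
#' consistency). Parsing is row-order independent: rows are sorted internally
#' by (plate, well, time). Empty `rfu` cells encode missed reads and flag the
#' trace as incomplete.
#'
#' @param source Path to a CSV file with columns `plate_id`, `well_id`,
#'   `sample_id`, `substrate_id`, `ph`, `replicate`, `role`, `time_min`, `rfu`.
#' @return A named list of [plate_run()] objects in canonical order (plates
#'   sorted by id, wells in natural plate order), independent of row order.
#' @seealso [write_kinetic_table()], [validate_layout()]
#' @export
read_kinetic_table <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), fileEncoding = "UTF-8")
  missing <- setdiff(kinetic_table_columns, names(df))
  if (length(missing))
    abort_format(paste0("kinetic table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  bad_role <- setdiff(unique(df$role), c("digestion", "intrinsic", "substrate_only", "empty"))
  if (length(bad_role))
    abort_format(paste0("unknown role value(s): ", paste(bad_role, collapse = ", ")))
  plates_from_long(df)
}

# Build plate_run objects from a long data frame (shared by the reader and
# the simulator).
plates_from_long <- function(df) {
  plate_order <- sort(unique(df$plate_id))
  runs <- lapply(plate_order, function(pid) {
    sub <- df[df$plate_id == pid, , drop = FALSE]
    well_order <- unique(sub$well_id)
    well_order <- well_order[order(well_sort_key(well_order))]
    traces <- lapply(well_order, function(wid) {
      w <- sub[sub$well_id == wid, , drop = FALSE]
      w <- w[order(w$time_min), , drop = FALSE]
      meta_cols <- unique(w[, c("sample_id", "substrate_id", "ph", "replicate", "role"),
                            drop = FALSE])
      if (nrow(meta_cols) != 1L)
        abort_format(sprintf("well %s on plate %s has inconsistent metadata across reads",
                             wid, pid))
      kinetic_trace(plate_id = pid, well_id = wid,
                    time_min = w$time_min, rfu = w$rfu,
                    role = meta_cols$role,
                    sample_id = meta_cols$sample_id,
                    substrate_id = meta_cols$substrate_id,
                    ph = meta_cols$ph,
                    replicate = if (is.na(meta_cols$replicate)) 1L else meta_cols$replicate)
    })
    tryCatch(plate_run(pid, traces),
             protrace_layout_error = function(e) stop_protrace(conditionMessage(e), "layout_error"))
  })
  names(runs) <- plate_order
  runs
}

#' Write plate runs as a long-format kinetics table
#'
#' Inverse of [read_kinetic_table()]: one row per (well, timepoint), RFC-4180
#' quoting, deterministic row order (plate, well, time), so identical inputs
#' always produce byte-identical files.
#'
#' @param runs A list of [plate_run()] objects (or a single one).
#' @param destination Output CSV path.
#' @return `destination`, invisibly.
#' @export
write_kinetic_table <- function(runs, destination) {
  if (inherits(runs, "plate_run")) runs <- list(runs)
  df <- kinetic_long_frame(runs)
  utils::write.csv(df, destination, row.names = FALSE, quote = TRUE,
                   na = "", fileEncoding = "UTF-8")
  invisible(destination)
}

# Long data frame across runs in canonical (plate, well, time) order.
kinetic_long_frame <- function(runs) {
  if (!length(runs)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(kinetic_table_columns)),
                                 kinetic_table_columns))
    df$ph <- numeric(0); df$replicate <- integer(0)
    df$time_min <- numeric(0); df$rfu <- numeric(0)
    return(df)
  }
  parts <- lapply(runs, function(run) {
    wells <- run$traces[order(well_sort_key(names(run$traces)))]
    do.call(rbind, lapply(wells, function(tr) {
      data.frame(plate_id = tr$plate_id, well_id = tr$well_id,
                 sample_id = tr$sample_id, substrate_id = tr$substrate_id,
                 ph = tr$ph, replicate = tr$replicate, role = tr$role,
                 time_min = tr$time_min, rfu = tr$rfu,
                 stringsAsFactors = FALSE)
    }))
  })
  parts <- parts[order(vapply(runs, function(r) r$plate_id, character(1)))]
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Natural well order: row letter then column number (A2 before A10).
well_sort_key <- function(well_id) {
  row <- substr(well_id, 1L, 1L)
  col <- suppressWarnings(as.integer(substring(well_id, 2L)))
  col[is.na(col)] <- 0L
  sprintf("%s%03d", row, col)
}

#' Read or write a sample sheet
#'
#' The sample sheet maps each extract to its cohort (e.g. HC, CD, UC, IBS) and
#' disease phase (`acute`, `remission`, or `none`). Sample ids must be unique
#' within a phase.
#'
#' @param source,destination CSV path.
#' @param sheet A sample-sheet data frame.
#' @return `read_sample_sheet()` returns a validated data frame with columns
#'   `sample_id`, `cohort`, `phase`, `notes`.
#' @export
read_sample_sheet <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), fileEncoding = "UTF-8")
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, destination) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.csv(sheet, destination, row.names = FALSE, quote = TRUE,
                   na = "", fileEncoding = "UTF-8")
  invisible(destination)
}

validate_sample_sheet <- function(df) {
  if (!all(c("sample_id", "cohort") %in% names(df)))
    abort_format("sample sheet needs columns 'sample_id' and 'cohort'")
  if (!"phase" %in% names(df)) df$phase <- "none"
  df$phase[is.na(df$phase)] <- "none"
  if (!all(df$phase %in% c("acute", "remission", "none")))
    abort_format("'phase' must be one of acute, remission, none")
  if (!"notes" %in% names(df)) df$notes <- NA_character_
  df$notes <- as.character(df$notes)
  key <- paste(df$sample_id, df$phase, sep = "\r")
  if (anyDuplicated(key))
    abort_format(paste0("duplicate sample_id within a phase: ",
                        paste(unique(df$sample_id[duplicated(key)]), collapse = ", ")))
  df[, c("sample_id", "cohort", "phase", "notes")]
}

#' Check consistency of plates, sample sheet, and substrate panel
#'
#' Performs structural cross-checks before analysis and returns the problems
#' found as data, not exceptions: sample ids on plates that are absent from
#' the sheet, digestion wells whose sample has no intrinsic-control well on
#' the same plate, plates without empty wells, and substrate ids not in the
#' panel.
#'
#' @param runs List of [plate_run()] objects.
#' @param sheet Sample sheet data frame (see [read_sample_sheet()]).
#' @param panel A [load_substrate_panel()] panel.
#' @return A data frame of issues with columns `issue`, `plate_id`,
#'   `sample_id`, `substrate_id`, `message`; zero rows when the layout is
#'   fully consistent.
#' @export
validate_layout <- function(runs, sheet, panel) {
  if (inherits(runs, "plate_run")) runs <- list(runs)
  issues <- list()
  add <- function(issue, plate_id = NA, sample_id = NA, substrate_id = NA, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      issue = issue, plate_id = as.character(plate_id),
      sample_id = as.character(sample_id), substrate_id = as.character(substrate_id),
      message = message, stringsAsFactors = FALSE)
  }
  for (run in runs) {
    roles <- plate_roles(run)
    if (!any(roles == "empty"))
      add("no_empty_wells", run$plate_id,
          message = sprintf("plate %s has no empty (buffer-only) well", run$plate_id))
    samples <- unique(stats::na.omit(vapply(run$traces, function(tr) tr$sample_id, character(1))))
    orphan <- setdiff(samples, sheet$sample_id)
    for (s in orphan)
      add("orphan_sample", run$plate_id, s,
          message = sprintf("sample %s on plate %s is not in the sample sheet", s, run$plate_id))
    intr_samples <- unique(vapply(plate_traces(run, "intrinsic"),
                                  function(tr) tr$sample_id, character(1)))
    dig <- plate_traces(run, "digestion")
    dig_samples <- unique(vapply(dig, function(tr) tr$sample_id, character(1)))
    for (s in setdiff(dig_samples, intr_samples))
      add("missing_intrinsic", run$plate_id, s,
          message = sprintf("sample %s has digestion wells but no intrinsic well on plate %s",
                            s, run$plate_id))
    subs <- unique(stats::na.omit(vapply(run$traces, function(tr) tr$substrate_id, character(1))))
    for (sub in setdiff(subs, panel$substrate_id))
      add("unknown_substrate", run$plate_id, substrate_id = sub,
          message = sprintf("substrate %s on plate %s is not in the panel", sub, run$plate_id))
  }
  if (!length(issues))
    return(data.frame(issue = character(0), plate_id = character(0),
                      sample_id = character(0), substrate_id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
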