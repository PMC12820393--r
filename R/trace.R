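#' Construct a single-well kinetic fluorescence trace
#'
#' A `kinetic_trace` is the atomic measurement of the assay: one well's
#' fluorescence time series (RFU versus minutes) together with its identity
#' (plate, well, sample, substrate, pH, replicate) and its role on the plate.
#' Well roles follow the standard plate design of AMC protease assays:
#' `digestion` wells contain extract plus substrate, `intrinsic` wells contain
#' extract without substrate (sample autofluorescence), `substrate_only` wells
#' contain substrate without extract, and `empty` wells carry only buffer and
#' measure the plate background used for normalization.
#'
#' @param plate_id,well_id Character scalars identifying the physical plate and
#'   well (e.g. `"A1"`).
#' @param time_min Strictly increasing read times in minutes; at least 4 reads.
#' @param rfu Fluorescence readings (relative fluorescence units), one per
#'   timepoint. `NA` encodes a missed read and marks the trace incomplete.
#' @param role One of `"digestion"`, `"intrinsic"`, `"substrate_only"`,
#'   `"empty"`.
#' @param sample_id,substrate_id Identity of the extract and substrate in the
#'   well; `NA` where the role implies absence (both `NA` for `empty` wells,
#'   `substrate_id` `NA` for `intrinsic` wells).
#' @param ph Assay buffer pH of the well.
#' @param replicate Replicate index (>= 1) within (sample, substrate, pH).
#' @param meta Free-form provenance list (generating parameters, applied
#'   corrections); carried along, never interpreted.
#'
#' @return An object of class `kinetic_trace`.
#' @seealso [plate_run()], [subtract_intrinsic()], [fit_slope()]
#' @export
kinetic_trace <- function(plate_id, well_id, time_min, rfu,
                          role = c("digestion", "intrinsic", "substrate_only", "empty"),
                          sample_id = NA_character_, substrate_id = NA_character_,
                          ph = NA_real_, replicate = 1L, meta = list()) {
  role <- match.arg(role)
  if (!is.character(plate_id) || length(plate_id) != 1L || is.na(plate_id))
    abort_input("'plate_id' must be a single non-missing string")
  if (!is.character(well_id) || length(well_id) != 1L || is.na(well_id))
    abort_input("'well_id' must be a single non-missing string")
  time_min <- as.numeric(time_min)
  rfu <- as.numeric(rfu)
  if (length(time_min) < 4L)
    abort_input("a kinetic trace needs at least 4 timepoints")
  if (anyNA(time_min) || any(diff(time_min) <= 0))
    abort_input("'time_min' must be strictly increasing and non-missing")
  if (length(rfu) != length(time_min))
    abort_input("'rfu' and 'time_min' must have the same length")
  if (any(is.infinite(rfu)))
    abort_input("'rfu' values must be finite (NA allowed for missed reads)")
  sample_id <- as.character(sample_id)
  substrate_id <- as.character(substrate_id)
  if (role == "digestion" && (is.na(sample_id) || is.na(substrate_id)))
    abort_input("digestion wells require both 'sample_id' and 'substrate_id'")
  if (role == "empty" && (!is.na(sample_id) || !is.na(substrate_id)))
    abort_input("empty wells must have no sample or substrate")
  if (role == "intrinsic" && (is.na(sample_id) || !is.na(substrate_id)))
    abort_input("intrinsic wells require 'sample_id' and no substrate")
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    abort_input("'replicate' must be an integer >= 1")
  structure(
    list(plate_id = plate_id, well_id = well_id,
         sample_id = sample_id, substrate_id = substrate_id,
         ph = as.numeric(ph), replicate = replicate, role = role,
         time_min = time_min, rfu = rfu,
         incomplete = anyNA(rfu), meta = meta),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> plate %s well %s [%s]\n", x$plate_id, x$well_id, x$role))
  if (!is.na(x$sample_id)) cat("  sample:   ", x$sample_id, "\n", sep = "")
  if (!is.na(x$substrate_id)) cat("  substrate:", x$substrate_id, " pH ", x$ph, "\n", sep = "")
  cat(sprintf("  %d reads over %g-%g min; RFU range [%g, %g]%s\n",
              length(x$time_min), min(x$time_min), max(x$time_min),
              min(x$rfu, na.rm = TRUE), max(x$rfu, na.rm = TRUE),
              if (x$incomplete) " (incomplete)" else ""))
  invisible(x)
}

#' Assemble traces from one physical plate
#'
#' A `plate_run` groups all wells read in one plate cycle: the unit of
#' normalization. Every trace must share the plate's timepoint grid, well ids
#' must be unique, and at least one `empty` (buffer-only) well is required so
#' that a normalization factor can be computed.
#'
#' @param plate_id Plate identifier; must match every trace's `plate_id`.
#' @param traces List of [kinetic_trace()] objects.
#' @param is_reference_plate Whether this plate is the designated reference
#'   whose empty-well mean defines the normalization reference value.
#' @param meta Free-form provenance list.
#' @return An object of class `plate_run`.
#' @export
plate_run <- function(plate_id, traces, is_reference_plate = FALSE, meta = list()) {
  if (!length(traces) || !all(vapply(traces, inherits, logical(1), "kinetic_trace")))
    abort_input("'traces' must be a non-empty list of kinetic_trace objects")
  if (!all(vapply(traces, function(tr) tr$plate_id, character(1)) == plate_id))
    abort_input("all traces must carry the plate's 'plate_id'")
  wells <- vapply(traces, function(tr) tr$well_id, character(1))
  if (anyDuplicated(wells))
    abort_layout(sprintf("duplicate well id(s) on plate %s: %s", plate_id,
                         paste(unique(wells[duplicated(wells)]), collapse = ", ")))
  grid <- traces[[1L]]$time_min
  same <- vapply(traces, function(tr) {
    length(tr$time_min) == length(grid) && all(tr$time_min == grid)
  }, logical(1))
  if (!all(same))
    abort_layout(sprintf("plate %s has ragged timepoint grids across wells", plate_id))
  # The presence of >= 1 empty (buffer-only) well is required for
  # normalization; it is enforced where the factor is computed and reported
  # by validate_layout(), so that malformed plates can still be inspected.
  names(traces) <- wells
  structure(
    list(plate_id = plate_id, traces = traces,
         is_reference_plate = isTRUE(is_reference_plate), meta = meta),
    class = "plate_run"
  )
}

#' @export
print.plate_run <- function(x, ...) {
  roles <- vapply(x$traces, function(tr) tr$role, character(1))
  cat(sprintf("<plate_run> %s: %d wells (%s)%s\n", x$plate_id, length(x$traces),
              paste(sprintf("%d %s", as.integer(table(roles)), names(table(roles))),
                    collapse = ", "),
              if (x$is_reference_plate) " [reference plate]" else ""))
  invisible(x)
}

# Flat accessors used across modules -------------------------------------

plate_roles <- function(plate) vapply(plate$traces, function(tr) tr$role, character(1))

plate_traces <- function(plate, role = NULL) {
  if (is.null(role)) return(plate$traces)
  plate$traces[plate_roles(plate) == role]
}

# All RFU reads from the empty wells of one plate, as one numeric vector.
empty_well_reads <- function(plate) {
  unlist(lapply(plate_traces(plate, "empty"), function(tr) tr$rfu), use.names = FALSE)
}
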