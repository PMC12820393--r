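#' Load a fluorogenic substrate panel
#'
#' The panel catalogues the AMC-labelled peptide substrates of the assay:
#' sequence, protease class (serine or cysteine), subclass (elastase-like,
#' furin-like, SKI-1/S1P-like, trypsin-like, cathepsin-like), the pH-optimum
#' range where one is established, and whether the peptide is custom-made or
#' commercially available. The built-in panel (the default) is the 14-substrate
#' catalogue used for fecal protease profiling; its per-subclass pH optima are
#' recorded on every member substrate and the two commercial substrates
#' (Pyr-RTKR-AMC, R-AMC) carry their catalogue aliases.
#'
#' @param source Path to a TSV/CSV file with columns `substrate_id`, `alias`,
#'   `sequence`, `protease_class`, `subclass`, `ph_opt_low`, `ph_opt_high`,
#'   `custom` (and optionally `derivation`); `NULL` (default) loads the
#'   packaged panel.
#' @return A `substrate_panel`: a data frame with one validated row per
#'   substrate.
#' @examples
#' panel <- load_substrate_panel()
#' nrow(panel)            # 14
#' table(panel$protease_class)
#' @export
load_substrate_panel <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "substrate_panel.tsv", package = "protrace",
                          mustWork = TRUE)
  sep <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(source, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          comment.char = "", fileEncoding = "UTF-8")
  validate_substrate_panel(df)
}

substrate_classes <- c("serine", "cysteine")
substrate_subclasses <- c("elastase-like", "furin-like", "SKI-1/S1P-like",
                          "trypsin-like", "cathepsin-like")

validate_substrate_panel <- function(df) {
  needed <- c("substrate_id", "sequence", "protease_class", "subclass",
              "ph_opt_low", "ph_opt_high", "custom")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    abort_format(paste0("substrate panel is missing column(s): ",
                        paste(missing, collapse = ", ")))
  if (anyDuplicated(df$substrate_id))
    abort_format(paste0("duplicate substrate id(s): ",
                        paste(unique(df$substrate_id[duplicated(df$substrate_id)]),
                              collapse = ", ")))
  if (!all(df$protease_class %in% substrate_classes))
    abort_format("'protease_class' must be 'serine' or 'cysteine'")
  if (!all(df$subclass %in% substrate_subclasses))
    abort_format(paste0("unknown subclass value(s): ",
                        paste(setdiff(df$subclass, substrate_subclasses), collapse = ", ")))
  # Catalytic consistency: cathepsin-like substrates probe cysteine proteases,
  # every other subclass probes serine proteases.
  cys_mismatch <- xor(df$subclass == "cathepsin-like", df$protease_class == "cysteine")
  if (any(cys_mismatch))
    abort_format(paste0("class/subclass mismatch for: ",
                        paste(df$substrate_id[cys_mismatch], collapse = ", "),
                        " (cathepsin-like substrates are cysteine-class, all others serine-class)"))
  bad_ph <- !is.na(df$ph_opt_low) & !is.na(df$ph_opt_high) & df$ph_opt_low > df$ph_opt_high
  if (any(bad_ph))
    abort_format("pH optimum range has low > high")
  if (!"alias" %in% names(df)) df$alias <- df$substrate_id
  df$custom <- as.logical(df$custom)
  class(df) <- c("substrate_panel", "data.frame")
  df
}

#' @export
print.substrate_panel <- function(x, ...) {
  cat(sprintf("<substrate_panel> %d substrates (%d serine, %d cysteine)\n",
              nrow(x), sum(x$protease_class == "serine"),
              sum(x$protease_class == "cysteine")))
  print.data.frame(x[, c("substrate_id", "protease_class", "subclass",
                         "ph_opt_low", "ph_opt_high", "custom")], row.names = FALSE)
  invisible(x)
}
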