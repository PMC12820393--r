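# Internal helpers: structured errors and seeded RNG scoping.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stop_protrace <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("protrace_", class), "protrace_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_input     <- function(msg) stop_protrace(msg, "input_error",     sys.call(-1))
abort_format    <- function(msg) stop_protrace(msg, "format_error",    sys.call(-1))
abort_layout    <- function(msg) stop_protrace(msg, "layout_error",    sys.call(-1))
abort_config    <- function(msg) stop_protrace(msg, "config_error",    sys.call(-1))
abort_pairing   <- function(msg) stop_protrace(msg, "pairing_error",   sys.call(-1))
abort_alignment <- function(msg) stop_protrace(msg, "alignment_error", sys.call(-1))
abort_integrity <- function(msg) stop_protrace(msg, "integrity_error", sys.call(-1))
abort_join      <- function(msg) stop_protrace(msg, "join_error",      sys.call(-1))
abort_lookup    <- function(msg) stop_protrace(msg, "lookup_error",    sys.call(-1))

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Stage seeds for the generator's documented substream scheme: the master
# seed deterministically yields one sub-seed per named stage.
stage_seeds <- function(seed, stages) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(stages))
    names(s) <- stages
    s
  })
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
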