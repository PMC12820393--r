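# Synthetic plate-reader data with ground truth.
#
# Generative model for one well:
#   RFU(t) = gain * (baseline + rate * tau * (1 - exp(-t / tau))) + eps,
#   eps ~ Normal(0, noise_sd^2), iid per read,
# whose tau -> Inf limit is the ideal linear progress curve
#   RFU(t) = gain * (baseline + rate * t) + eps.
# The single-exponential product-formation term is the simplest curve with an
# exactly linear early phase followed by substrate-depletion saturation.

#' Configure a synthetic protease-profiling study
#'
#' Builds the parameter set for [simulate_study()]: cohort sizes, the
#' substrate panel and pH conditions, the mean activity-rate surface, and the
#' nuisance structure the analysis pipeline has to cope with (lognormal
#' inter-individual variability, per-sample intrinsic background with a
#' high-background subpopulation, per-plate gain differences, additive read
#' noise, saturating traces).
#'
#' Defaults emulate the profiling study design: cohorts HC/CD/UC/IBS of sizes
#' 12/12/11/4, the 14-substrate panel, pH 5.5/6.5/7.5/8.0, triplicate wells
#' read every 5 min for 75 min, and a 20% high-background subpopulation.
#'
#' @param cohorts Named integer vector of samples per cohort.
#' @param panel Substrate panel (default [load_substrate_panel()]).
#' @param ph_levels Assay pH conditions.
#' @param effect_matrix Data frame `(cohort, substrate_id, ph, rate)` of mean
#'   activity rates in RFU/min; must cover every (cohort, substrate, pH) cell.
#'   Default [default_effect_matrix()], an illustrative surface (not measured
#'   values).
#' @param cv_log Lognormal inter-individual coefficient of variation of true
#'   rates (unitless, >= 0). The lognormal multiplier has mean exactly 1, so
#'   cohort means stay calibrated to `effect_matrix`.
#' @param depletion_tau_min Substrate-depletion timescale tau in minutes
#'   (`Inf` = ideal linear traces). Either a scalar or a data frame
#'   `(substrate_id, ph, tau)` per condition.
#' @param noise_sd_rfu Additive Gaussian read noise SD (RFU).
#' @param background_mean_rfu,background_sd_rfu Mean/SD of the per-sample
#'   intrinsic fluorescence baseline (lognormal, RFU).
#' @param high_background_fraction Probability a sample is a high-background
#'   ("mesalazine-like") extract.
#' @param high_background_multiplier Baseline inflation factor for
#'   high-background samples.
#' @param plate_gain_sd Lognormal SD (sdlog) of the per-plate gain; gains have
#'   mean 1.
#' @param empty_well_rfu Plate background level of buffer-only wells (RFU).
#' @param substrate_blank_rfu Signal of substrate-only wells above the plate
#'   background (RFU).
#' @param replicates Digestion wells per (sample, substrate, pH).
#' @param timepoints_min Read times in minutes (strictly increasing, >= 4).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(cohorts = c(HC = 12L, CD = 12L, UC = 11L, IBS = 4L),
                       panel = load_substrate_panel(),
                       ph_levels = c(5.5, 6.5, 7.5, 8.0),
                       effect_matrix = default_effect_matrix(names(cohorts), panel, ph_levels),
                       cv_log = 0.6,
                       depletion_tau_min = 60,
                       noise_sd_rfu = 5,
                       background_mean_rfu = 25,
                       background_sd_rfu = 8,
                       high_background_fraction = 0.2,
                       high_background_multiplier = 50,
                       plate_gain_sd = 0.05,
                       empty_well_rfu = 100,
                       substrate_blank_rfu = 10,
                       replicates = 3L,
                       timepoints_min = seq(0, 75, by = 5),
                       seed = 1L) {
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    abort_config("'cohorts' must be a named vector of sample counts")
  cohorts <- vapply(cohorts, as.integer, integer(1))
  if (any(cohorts < 1L)) abort_config("all cohort sizes must be >= 1")
  panel <- validate_substrate_panel(as.data.frame(panel))
  if (!length(ph_levels) || anyNA(ph_levels))
    abort_config("'ph_levels' must be non-missing pH values")
  if (!is_number(cv_log) || cv_log < 0) abort_config("'cv_log' must be >= 0")
  if (!is_number(noise_sd_rfu) || noise_sd_rfu < 0)
    abort_config("'noise_sd_rfu' must be >= 0")
  if (!is_number(high_background_fraction) ||
      high_background_fraction < 0 || high_background_fraction > 1)
    abort_config("'high_background_fraction' must be in [0, 1]")
  if (!is_number(high_background_multiplier) || high_background_multiplier < 1)
    abort_config("'high_background_multiplier' must be >= 1")
  if (!is_number(plate_gain_sd) || plate_gain_sd < 0)
    abort_config("'plate_gain_sd' must be >= 0")
  if (!is_number(background_mean_rfu) || background_mean_rfu < 0 ||
      !is_number(background_sd_rfu) || background_sd_rfu < 0)
    abort_config("background mean/sd must be >= 0")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) abort_config("'replicates' must be >= 1")
  timepoints_min <- as.numeric(timepoints_min)
  if (length(timepoints_min) < 4L || any(diff(timepoints_min) <= 0))
    abort_config("'timepoints_min' must be strictly increasing with >= 4 points")
  effect_matrix <- validate_effect_matrix(effect_matrix, names(cohorts),
                                          panel$substrate_id, ph_levels)
  tau_fun <- tau_lookup(depletion_tau_min, panel$substrate_id, ph_levels)
  structure(
    list(cohorts = cohorts, panel = panel, ph_levels = ph_levels,
         effect_matrix = effect_matrix, cv_log = cv_log,
         depletion_tau_min = depletion_tau_min, tau_fun = tau_fun,
         noise_sd_rfu = noise_sd_rfu,
         background_mean_rfu = background_mean_rfu,
         background_sd_rfu = background_sd_rfu,
         high_background_fraction = high_background_fraction,
         high_background_multiplier = high_background_multiplier,
         plate_gain_sd = plate_gain_sd,
         empty_well_rfu = empty_well_rfu,
         substrate_blank_rfu = substrate_blank_rfu,
         replicates = replicates, timepoints_min = timepoints_min,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

validate_effect_matrix <- function(em, cohorts, substrates, ph_levels) {
  needed <- c("cohort", "substrate_id", "ph", "rate")
  if (!is.data.frame(em) || !all(needed %in% names(em)))
    abort_config("effect matrix must be a data frame with columns cohort, substrate_id, ph, rate")
  if (any(em$rate < 0)) abort_config("effect-matrix rates must be >= 0")
  want <- expand.grid(cohort = cohorts, substrate_id = substrates, ph = ph_levels,
                      stringsAsFactors = FALSE)
  key_have <- paste(em$cohort, em$substrate_id, em$ph)
  key_want <- paste(want$cohort, want$substrate_id, want$ph)
  miss <- setdiff(key_want, key_have)
  if (length(miss))
    abort_config(paste0("effect matrix is missing ", length(miss),
                        " (cohort, substrate, pH) cell(s), e.g. ", miss[1L]))
  if (anyDuplicated(key_have))
    abort_config("effect matrix has duplicate (cohort, substrate, pH) cells")
  em[, needed]
}

# Closure mapping (substrate, ph) -> tau.
tau_lookup <- function(tau, substrates, ph_levels) {
  if (is.data.frame(tau)) {
    if (!all(c("substrate_id", "ph", "tau") %in% names(tau)))
      abort_config("per-condition tau needs columns substrate_id, ph, tau")
    if (any(tau$tau <= 0)) abort_config("tau must be > 0 (Inf allowed)")
    key <- paste(tau$substrate_id, tau$ph)
    function(s, p) {
      i <- match(paste(s, p), key)
      if (is.na(i)) abort_config(sprintf("no tau for (%s, pH %s)", s, p))
      tau$tau[i]
    }
  } else {
    if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0)
      abort_config("'depletion_tau_min' must be a positive scalar (Inf allowed) or a data frame")
    function(s, p) tau
  }
}

#' Illustrative mean-activity surface for the simulator
#'
#' Mean rates (RFU/min) per (cohort, substrate, pH) qualitatively mirroring
#' the trends of cohort-level fecal protease profiling: healthy controls near
#' zero everywhere; CD and UC broadly elevated across serine and cysteine
#' substrates with UC showing stronger cathepsin-like activity (including the
#' RSVL substrate at pH 5.5); IBS dominated by furin-like substrates, peaking
#' at pH 8.0; pH 5.5 globally the least active condition. These values are an
#' illustrative fixture for simulation and testing -- they are NOT measured
#' data.
#'
#' @param cohorts Cohort labels; the built-in shapes exist for HC, CD, UC,
#'   IBS, and any other label falls back to the HC (low-activity) shape.
#' @param panel Substrate panel.
#' @param ph_levels pH conditions.
#' @return Data frame `(cohort, substrate_id, ph, rate)` covering the full
#'   grid.
#' @export
default_effect_matrix <- function(cohorts = c("HC", "CD", "UC", "IBS"),
                                  panel = load_substrate_panel(),
                                  ph_levels = c(5.5, 6.5, 7.5, 8.0)) {
  grid <- expand.grid(cohort = cohorts, substrate_id = panel$substrate_id,
                      ph = ph_levels, stringsAsFactors = FALSE)
  grid$subclass <- panel$subclass[match(grid$substrate_id, panel$substrate_id)]
  base <- function(cohort, subclass) {
    switch(cohort,
      CD = switch(subclass, "elastase-like" = 40, "furin-like" = 300,
                  "SKI-1/S1P-like" = 220, "trypsin-like" = 180,
                  "cathepsin-like" = 170),
      UC = switch(subclass, "elastase-like" = 50, "furin-like" = 260,
                  "SKI-1/S1P-like" = 200, "trypsin-like" = 160,
                  "cathepsin-like" = 260),
      IBS = switch(subclass, "elastase-like" = 20, "furin-like" = 420,
                   "SKI-1/S1P-like" = 80, "trypsin-like" = 60,
                   "cathepsin-like" = 40),
      # HC and unknown labels: negligible activity everywhere
      switch(subclass, "elastase-like" = 4, "furin-like" = 8,
             "SKI-1/S1P-like" = 6, "trypsin-like" = 6, "cathepsin-like" = 5))
  }
  # pH modulation: activity lowest at pH 5.5, rising toward neutral/basic pH;
  # cathepsin-like (cysteine) substrates instead peak at mildly acidic pH;
  # IBS furin-like activity peaks at pH 8.0.
  ph_mod <- function(cohort, subclass, ph) {
    if (subclass == "cathepsin-like") {
      c("5.5" = 0.45, "6.5" = 1, "7.5" = 1, "8" = 0.5)[[as.character(ph)]]
    } else if (cohort == "IBS" && subclass == "furin-like") {
      c("5.5" = 0.25, "6.5" = 0.9, "7.5" = 0.7, "8" = 1.1)[[as.character(ph)]]
    } else {
      c("5.5" = 0.15, "6.5" = 0.8, "7.5" = 1, "8" = 0.9)[[as.character(ph)]]
    }
  }
  grid$rate <- mapply(function(cohort, subclass, ph)
    base(cohort, subclass) * ph_mod(cohort, subclass, ph),
    grid$cohort, grid$subclass, grid$ph)
  # UC-specific preference for the RSVL cathepsin substrate at pH 5.5 (the
  # single-substrate UC-vs-CD discriminator construct).
  sel <- grid$cohort == "UC" & grid$substrate_id == "RSVL-AMC" & grid$ph == 5.5
  grid$rate[sel] <- grid$rate[sel] * 2.2
  grid[, c("cohort", "substrate_id", "ph", "rate")]
}

#' Simulate one kinetic fluorescence trace
#'
#' Draws a single well's progress curve from the generator's model:
#' `RFU(t) = gain * (baseline + rate * tau * (1 - exp(-t / tau))) + eps` with
#' iid Gaussian read noise; `tau = Inf` gives the ideal linear trace
#' `gain * (baseline + rate * t)`. Generating parameters are recorded in the
#' trace's `meta$sim` provenance.
#'
#' @param rate True activity rate in RFU/min (>= 0).
#' @param baseline Constant intrinsic baseline in RFU (>= 0).
#' @param gain Multiplicative plate gain (> 0).
#' @param depletion_tau_min Saturation timescale tau in minutes (> 0 or
#'   `Inf`).
#' @param noise_sd Read-noise SD in RFU (>= 0).
#' @param timepoints_min Read times (strictly increasing, >= 4 points).
#' @param seed Optional seed for the noise draws; `NULL` uses the current RNG
#'   stream.
#' @param plate_id,well_id,role,sample_id,substrate_id,ph,replicate Identity
#'   metadata passed to [kinetic_trace()].
#' @return A [kinetic_trace()].
#' @examples
#' tr <- simulate_kinetic_trace(rate = 3, baseline = 10, noise_sd = 0)
#' tail(tr$rfu, 1)  # 10 + 3 * 75 = 235
#' @export
simulate_kinetic_trace <- function(rate, baseline, gain = 1,
                                   depletion_tau_min = Inf, noise_sd = 0,
                                   timepoints_min = seq(0, 75, by = 5),
                                   seed = NULL,
                                   plate_id = "SIM", well_id = "A1",
                                   role = "digestion",
                                   sample_id = "S1", substrate_id = "SUB",
                                   ph = 7.5, replicate = 1L) {
  if (!is_number(rate) || rate < 0) abort_input("'rate' must be a number >= 0")
  if (!is_number(baseline) || baseline < 0) abort_input("'baseline' must be a number >= 0")
  if (!is_number(gain) || gain <= 0) abort_input("'gain' must be > 0")
  if (!is_number(noise_sd) || noise_sd < 0) abort_input("'noise_sd' must be >= 0")
  if (!(is_number(depletion_tau_min) || identical(depletion_tau_min, Inf)) ||
      depletion_tau_min <= 0)
    abort_input("'depletion_tau_min' must be > 0 (Inf for ideal linear)")
  timepoints_min <- as.numeric(timepoints_min)
  if (length(timepoints_min) < 4L || anyNA(timepoints_min) ||
      any(diff(timepoints_min) <= 0))
    abort_input("'timepoints_min' must be strictly increasing with >= 4 points")
  signal <- gain * (baseline + product_curve(rate, depletion_tau_min, timepoints_min))
  eps <- if (noise_sd > 0) {
    if (is.null(seed)) stats::rnorm(length(timepoints_min), 0, noise_sd)
    else with_seed(seed, stats::rnorm(length(timepoints_min), 0, noise_sd))
  } else rep(0, length(timepoints_min))
  kinetic_trace(plate_id = plate_id, well_id = well_id,
                time_min = timepoints_min, rfu = signal + eps, role = role,
                sample_id = if (role %in% c("digestion", "intrinsic")) sample_id else NA_character_,
                substrate_id = if (role %in% c("digestion", "substrate_only")) substrate_id else NA_character_,
                ph = ph, replicate = replicate,
                meta = list(sim = list(rate = rate, baseline = baseline, gain = gain,
                                       tau = depletion_tau_min, noise_sd = noise_sd)))
}

# Product-formation term: rate * tau * (1 - exp(-t / tau)); linear limit at
# tau = Inf. Written to be exact (no 0 * Inf) in the linear limit.
product_curve <- function(rate, tau, t) {
  if (is.infinite(tau)) rate * t else rate * tau * (1 - exp(-t / tau))
}

#' Simulate a full profiling study with ground truth
#'
#' Generates one plate per (sample, pH condition): `replicates` digestion
#' wells per substrate, one intrinsic (extract-only) well for the sample, one
#' substrate-only well per substrate, and two empty buffer wells. True rates
#' are `v = mu[cohort, substrate, pH] * LogNormal` with unit-mean lognormal
#' inter-individual multipliers; intrinsic baselines are lognormal with a
#' Bernoulli high-background subpopulation; plate gains are lognormal with
#' mean 1. All randomness derives from `config$seed` through documented stage
#' substreams (flags, baselines, rates, gains, noise), so identical configs
#' reproduce identical datasets.
#'
#' @param config A [sim_config()].
#' @return A list of class `ppa_simulation` with elements `plates` (list of
#'   [plate_run()]), `sheet` (sample sheet), `truth` (list: `samples` with
#'   per-sample baseline and high-background flag, `rates` with true
#'   per-sample rates, `plates` with per-plate gains, `seed`), and `config`.
#' @seealso [simulate_inhibition_experiment()], [fit_activity()]
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sheet <- data.frame(
    sample_id = unlist(lapply(names(config$cohorts), function(co)
      sprintf("%s%02d", co, seq_len(config$cohorts[[co]])))),
    cohort = rep(names(config$cohorts), config$cohorts),
    phase = "none", notes = NA_character_, stringsAsFactors = FALSE)
  n <- nrow(sheet)
  seeds <- stage_seeds(config$seed, c("flags", "baselines", "rates", "gains", "noise"))

  high <- with_seed(seeds[["flags"]],
                    stats::rbinom(n, 1L, config$high_background_fraction) == 1L)
  base_i <- with_seed(seeds[["baselines"]],
                      rlnorm_meansd(n, config$background_mean_rfu, config$background_sd_rfu))
  base_i[high] <- base_i[high] * config$high_background_multiplier

  subs <- config$panel$substrate_id
  grid <- expand.grid(substrate_id = subs, ph = config$ph_levels,
                      stringsAsFactors = FALSE)  # substrate-major within pH
  mu_key <- paste(config$effect_matrix$cohort, config$effect_matrix$substrate_id,
                  config$effect_matrix$ph)
  # True rates, sample-major then (substrate, ph) in grid order.
  sdlog <- sqrt(log1p(config$cv_log^2))
  mult <- with_seed(seeds[["rates"]], {
    if (sdlog == 0) rep(1, n * nrow(grid))
    else stats::rlnorm(n * nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  rates <- do.call(rbind, lapply(seq_len(n), function(i) {
    mu <- config$effect_matrix$rate[match(paste(sheet$cohort[i], grid$substrate_id, grid$ph),
                                          mu_key)]
    data.frame(sample_id = sheet$sample_id[i], substrate_id = grid$substrate_id,
               ph = grid$ph, rate = mu * mult[(i - 1L) * nrow(grid) + seq_len(nrow(grid))],
               stringsAsFactors = FALSE)
  }))

  plate_index <- expand.grid(sample = seq_len(n), ph = config$ph_levels)
  plate_index <- plate_index[order(plate_index$sample, plate_index$ph), , drop = FALSE]
  gains <- with_seed(seeds[["gains"]], {
    if (config$plate_gain_sd == 0) rep(1, nrow(plate_index))
    else stats::rlnorm(nrow(plate_index), meanlog = -config$plate_gain_sd^2 / 2,
                       sdlog = config$plate_gain_sd)
  })

  rate_key <- paste(rates$sample_id, rates$substrate_id, rates$ph)
  plates <- vector("list", nrow(plate_index))
  plate_meta <- vector("list", nrow(plate_index))
  with_seed(seeds[["noise"]], {
    for (k in seq_len(nrow(plate_index))) {
      i <- plate_index$sample[k]
      ph <- plate_index$ph[k]
      sid <- sheet$sample_id[i]
      pid <- sprintf("P%03d_pH%s", k, format(ph, nsmall = 1))
      g <- gains[k]
      specs <- plate_well_specs(config, sid, ph)
      v <- rates$rate[match(paste(sid, specs$substrate_id, ph), rate_key)]
      traces <- vector("list", nrow(specs))
      for (w in seq_len(nrow(specs))) {
        role <- specs$role[w]
        rate_w <- switch(role, digestion = v[w], 0)
        baseline_w <- config$empty_well_rfu +
          switch(role, digestion = base_i[i], intrinsic = base_i[i],
                 substrate_only = config$substrate_blank_rfu, empty = 0)
        traces[[w]] <- simulate_kinetic_trace(
          rate = rate_w, baseline = baseline_w, gain = g,
          depletion_tau_min = if (role == "digestion")
            config$tau_fun(specs$substrate_id[w], ph) else Inf,
          noise_sd = config$noise_sd_rfu,
          timepoints_min = config$timepoints_min,
          plate_id = pid, well_id = specs$well_id[w], role = role,
          sample_id = sid, substrate_id = specs$substrate_id[w],
          ph = ph, replicate = specs$replicate[w])
      }
      plates[[k]] <- plate_run(pid, traces,
                               is_reference_plate = (k == 1L),
                               meta = list(gain = g, sample_id = sid, ph = ph))
      plate_meta[[k]] <- data.frame(plate_id = pid, sample_id = sid, ph = ph,
                                    gain = g, stringsAsFactors = FALSE)
    }
  })
  names(plates) <- vapply(plates, function(p) p$plate_id, character(1))
  truth <- list(
    samples = data.frame(sample_id = sheet$sample_id, cohort = sheet$cohort,
                         baseline_rfu = base_i, high_background = high,
                         stringsAsFactors = FALSE),
    rates = rates,
    plates = do.call(rbind, plate_meta),
    seed = config$seed)
  structure(list(plates = plates, sheet = sheet, truth = truth, config = config),
            class = "ppa_simulation")
}

#' @export
print.ppa_simulation <- function(x, ...) {
  cat(sprintf("<ppa_simulation> %d samples (%s), %d plates, %d substrates x %d pH, seed %d\n",
              nrow(x$sheet),
              paste(sprintf("%s=%d", names(x$config$cohorts), x$config$cohorts), collapse = ", "),
              length(x$plates), nrow(x$config$panel), length(x$config$ph_levels),
              x$config$seed))
  invisible(x)
}

# Deterministic well layout of one simulated plate: digestion wells
# (substrate-major, replicates within), one intrinsic well, one
# substrate-only well per substrate, two empty wells. Well ids run row-major
# A1..A12, B1..H12.
plate_well_specs <- function(config, sample_id, ph) {
  subs <- config$panel$substrate_id
  reps <- config$replicates
  specs <- rbind(
    data.frame(role = "digestion",
               substrate_id = rep(subs, each = reps),
               replicate = rep(seq_len(reps), times = length(subs)),
               stringsAsFactors = FALSE),
    data.frame(role = "intrinsic", substrate_id = NA_character_, replicate = 1L),
    data.frame(role = "substrate_only", substrate_id = subs, replicate = 1L),
    data.frame(role = c("empty", "empty"), substrate_id = NA_character_,
               replicate = c(1L, 2L)))
  if (nrow(specs) > 96L)
    abort_config(sprintf("plate layout needs %d wells (> 96); reduce substrates or replicates",
                         nrow(specs)))
  idx <- seq_len(nrow(specs)) - 1L
  specs$well_id <- sprintf("%s%d", LETTERS[idx %/% 12L + 1L], idx %% 12L + 1L)
  specs
}

# Lognormal with prescribed arithmetic mean and SD (degenerate cases exact).
rlnorm_meansd <- function(n, mean, sd) {
  if (mean == 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p((sd / mean)^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a paired inhibitor/control experiment
#'
#' Emulates the furin-inhibition design: each sample's extract is assayed
#' against one substrate at one pH with and without an irreversible inhibitor,
#' in paired wells on the same plate. The inhibited true rate is
#' `v_inh = v * (1 - furin_fraction * inhibitor_efficiency)`, where
#' `furin_fraction` is the share of the substrate's cleavage attributable to
#' the inhibited (furin-like) class and `inhibitor_efficiency` the fraction of
#' that class actually blocked.
#'
#' @param config A [sim_config()]; cohort structure, panel, noise and
#'   background parameters are reused.
#' @param furin_fraction Fraction of activity attributable to the inhibited
#'   class, in `[0, 1]`.
#' @param inhibitor_efficiency Fraction of that class blocked, in `[0, 1]`.
#' @param substrate_id,ph Assay condition (default the furin probe RTKR-AMC
#'   at pH 7.5).
#' @param seed Seed for this experiment (default `config$seed + 1`).
#' @return A list of class `ppa_inhibition_sim`: `plates` (one per sample,
#'   with paired control/inhibitor digestion wells distinguished by
#'   `meta$condition` and `meta$condition` recorded per trace), `sheet`,
#'   `truth` (per-sample control and inhibited rates), `substrate_id`, `ph`.
#' @export
simulate_inhibition_experiment <- function(config, furin_fraction,
                                           inhibitor_efficiency,
                                           substrate_id = "RTKR-AMC", ph = 7.5,
                                           seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is_number(furin_fraction) || furin_fraction < 0 || furin_fraction > 1)
    abort_input("'furin_fraction' must be in [0, 1]")
  if (!is_number(inhibitor_efficiency) || inhibitor_efficiency < 0 || inhibitor_efficiency > 1)
    abort_input("'inhibitor_efficiency' must be in [0, 1]")
  if (!substrate_id %in% config$panel$substrate_id)
    abort_lookup(sprintf("substrate %s is not in the panel", substrate_id))
  sheet <- data.frame(
    sample_id = unlist(lapply(names(config$cohorts), function(co)
      sprintf("%s%02d", co, seq_len(config$cohorts[[co]])))),
    cohort = rep(names(config$cohorts), config$cohorts),
    phase = "none", notes = NA_character_, stringsAsFactors = FALSE)
  n <- nrow(sheet)
  seeds <- stage_seeds(seed, c("flags", "baselines", "rates", "gains", "noise"))
  base_i <- with_seed(seeds[["baselines"]],
                      rlnorm_meansd(n, config$background_mean_rfu, config$background_sd_rfu))
  mu_key <- paste(config$effect_matrix$cohort, config$effect_matrix$substrate_id,
                  config$effect_matrix$ph)
  mu <- config$effect_matrix$rate[match(paste(sheet$cohort, substrate_id, ph), mu_key)]
  if (anyNA(mu))
    abort_config(sprintf("effect matrix has no cell for (%s, pH %s)", substrate_id, ph))
  sdlog <- sqrt(log1p(config$cv_log^2))
  v <- with_seed(seeds[["rates"]], {
    m <- if (sdlog == 0) rep(1, n)
         else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    mu * m
  })
  v_inh <- v * (1 - furin_fraction * inhibitor_efficiency)
  gains <- with_seed(seeds[["gains"]], {
    if (config$plate_gain_sd == 0) rep(1, n)
    else stats::rlnorm(n, meanlog = -config$plate_gain_sd^2 / 2,
                       sdlog = config$plate_gain_sd)
  })
  reps <- config$replicates
  plates <- vector("list", n)
  with_seed(seeds[["noise"]], {
    for (i in seq_len(n)) {
      sid <- sheet$sample_id[i]
      pid <- sprintf("INH%03d", i)
      conditions <- data.frame(
        condition = rep(c("control", "inhibitor"), each = reps),
        rate = rep(c(v[i], v_inh[i]), each = reps),
        replicate = rep(seq_len(reps), times = 2L), stringsAsFactors = FALSE)
      traces <- vector("list", nrow(conditions) + 3L)
      for (w in seq_len(nrow(conditions))) {
        traces[[w]] <- simulate_kinetic_trace(
          rate = conditions$rate[w], baseline = config$empty_well_rfu + base_i[i],
          gain = gains[i], depletion_tau_min = config$tau_fun(substrate_id, ph),
          noise_sd = config$noise_sd_rfu, timepoints_min = config$timepoints_min,
          plate_id = pid, well_id = sprintf("A%d", w), role = "digestion",
          sample_id = sid, substrate_id = substrate_id, ph = ph,
          replicate = conditions$replicate[w])
        traces[[w]]$meta$condition <- conditions$condition[w]
      }
      traces[[nrow(conditions) + 1L]] <- simulate_kinetic_trace(
        rate = 0, baseline = config$empty_well_rfu + base_i[i], gain = gains[i],
        depletion_tau_min = Inf, noise_sd = config$noise_sd_rfu,
        timepoints_min = config$timepoints_min, plate_id = pid, well_id = "B1",
        role = "intrinsic", sample_id = sid, ph = ph)
      traces[[nrow(conditions) + 2L]] <- simulate_kinetic_trace(
        rate = 0, baseline = config$empty_well_rfu + config$substrate_blank_rfu,
        gain = gains[i], depletion_tau_min = Inf, noise_sd = config$noise_sd_rfu,
        timepoints_min = config$timepoints_min, plate_id = pid, well_id = "B2",
        role = "substrate_only", substrate_id = substrate_id, ph = ph)
      traces[[nrow(conditions) + 3L]] <- simulate_kinetic_trace(
        rate = 0, baseline = config$empty_well_rfu, gain = gains[i],
        depletion_tau_min = Inf, noise_sd = config$noise_sd_rfu,
        timepoints_min = config$timepoints_min, plate_id = pid, well_id = "B3",
        role = "empty", ph = ph)
      plates[[i]] <- plate_run(pid, traces, is_reference_plate = (i == 1L),
                               meta = list(gain = gains[i], sample_id = sid, ph = ph))
    }
  })
  names(plates) <- vapply(plates, function(p) p$plate_id, character(1))
  structure(
    list(plates = plates, sheet = sheet,
         truth = data.frame(sample_id = sheet$sample_id, cohort = sheet$cohort,
                            control_rate = v, inhibited_rate = v_inh,
                            baseline_rfu = base_i, gain = gains,
                            stringsAsFactors = FALSE),
         substrate_id = substrate_id, ph = ph,
         furin_fraction = furin_fraction,
         inhibitor_efficiency = inhibitor_efficiency, seed = seed),
    class = "ppa_inhibition_sim")
}

#' Write a simulated study to disk
#'
#' Emits the tidy kinetics CSV, the sample-sheet CSV, and the ground-truth
#' sidecars (per-sample truth and per-condition true rates as CSV) into a
#' directory.
#'
#' @param sim A `ppa_simulation` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ppa_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(kinetics = file.path(dir, "kinetics.csv"),
             sheet = file.path(dir, "sample_sheet.csv"),
             truth_samples = file.path(dir, "truth_samples.csv"),
             truth_rates = file.path(dir, "truth_rates.csv"))
  write_kinetic_table(sim$plates, paths[["kinetics"]])
  write_sample_sheet(sim$sheet, paths[["sheet"]])
  utils::write.csv(sim$truth$samples, paths[["truth_samples"]], row.names = FALSE)
  utils::write.csv(sim$truth$rates, paths[["truth_rates"]], row.names = FALSE)
  invisible(paths)
}
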