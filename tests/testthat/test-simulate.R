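test_that("noiseless trace generation follows the closed-form model", {
  t <- seq(0, 75, by = 5)
  # ideal linear limit
  tr <- simulate_kinetic_trace(rate = 3, baseline = 10, gain = 1,
                               depletion_tau_min = Inf, noise_sd = 0,
                               timepoints_min = t)
  expect_equal(tr$rfu, 10 + 3 * t)
  expect_equal(tr$rfu[t == 75], 235)
  # zero rate with gain: flat at gain * baseline
  tr0 <- simulate_kinetic_trace(rate = 0, baseline = 10, gain = 2, noise_sd = 0)
  expect_equal(tr0$rfu, rep(20, 16))
  # saturating curve against an independent closed-form evaluation
  tau <- 30
  tr_sat <- simulate_kinetic_trace(rate = 3, baseline = 0, gain = 1,
                                   depletion_tau_min = tau, noise_sd = 0,
                                   timepoints_min = t)
  expect_equal(tr_sat$rfu, 3 * tau * (1 - exp(-t / tau)))
  expect_equal(tr_sat$rfu[t == 75], 3 * 30 * (1 - exp(-2.5)))
  # gain realism: doubling the gain exactly doubles every read
  tr_g <- simulate_kinetic_trace(rate = 3, baseline = 10, gain = 2, noise_sd = 0)
  expect_equal(tr_g$rfu, 2 * tr$rfu)
})

test_that("trace generation rejects invalid inputs", {
  expect_error(simulate_kinetic_trace(rate = -1, baseline = 0),
               class = "protrace_input_error")
  expect_error(simulate_kinetic_trace(rate = 1, baseline = -5),
               class = "protrace_input_error")
  expect_error(simulate_kinetic_trace(rate = 1, baseline = 0,
                                      timepoints_min = c(0, 5, 5, 10)),
               class = "protrace_input_error")
  expect_error(simulate_kinetic_trace(rate = 1, baseline = 0,
                                      timepoints_min = c(0, 5, 10)),
               class = "protrace_input_error")
})

test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- tiny_config(seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth, b$truth)
  expect_identical(a$plates$P001_pH7.5$traces$A1$rfu,
                   b$plates$P001_pH7.5$traces$A1$rfu)
  expect_equal(a$plates, b$plates)
  # a different seed changes the data
  c <- simulate_study(tiny_config(seed = 100))
  expect_false(identical(a$plates$P001_pH7.5$traces$A1$rfu,
                         c$plates$P001_pH7.5$traces$A1$rfu))
})

test_that("degenerate no-noise study yields digestion slopes equal to the effect matrix", {
  cfg <- sim_config(cohorts = c(HC = 2L, CD = 2L), ph_levels = c(5.5, 7.5),
                    cv_log = 0, noise_sd_rfu = 0, plate_gain_sd = 0,
                    depletion_tau_min = Inf, high_background_fraction = 0,
                    replicates = 2L, seed = 5)
  sim <- simulate_study(cfg)
  mu_key <- paste(cfg$effect_matrix$cohort, cfg$effect_matrix$substrate_id,
                  cfg$effect_matrix$ph)
  for (plate in sim$plates) {
    for (tr in plate_traces(plate, "digestion")) {
      co <- sim$sheet$cohort[match(tr$sample_id, sim$sheet$sample_id)]
      mu <- cfg$effect_matrix$rate[match(paste(co, tr$substrate_id, tr$ph), mu_key)]
      slope <- unname(stats::coef(stats::lm(tr$rfu ~ tr$time_min))[2L])
      expect_equal(slope, mu, tolerance = 1e-10)
    }
  }
})

test_that("high-background flags regenerate from the documented seed derivation", {
  cfg <- sim_config(cohorts = c(HC = 20L, CD = 20L), ph_levels = 7.5,
                    replicates = 1L, high_background_fraction = 0.2, seed = 31)
  sim <- simulate_study(cfg)
  # re-derive stage seeds exactly as documented: master seed -> 5 sub-seeds,
  # the first of which drives the Bernoulli flag stream
  set.seed(31)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 5L)
  set.seed(sub_seeds[1L])
  flags <- stats::rbinom(40L, 1L, 0.2) == 1L
  expect_identical(sim$truth$samples$high_background, flags)
  expect_equal(sum(sim$truth$samples$high_background), sum(flags))
})

test_that("lognormal rate variability is calibrated in the mean", {
  cfg <- sim_config(cohorts = c(CD = 500L),
                    panel = load_substrate_panel()[3L, ],
                    ph_levels = 7.5, replicates = 1L, cv_log = 0.6,
                    noise_sd_rfu = 0, plate_gain_sd = 0,
                    high_background_fraction = 0, seed = 17)
  sim <- simulate_study(cfg)
  mu <- cfg$effect_matrix$rate[1L]
  ratio <- sim$truth$rates$rate / mu
  se <- stats::sd(ratio) / sqrt(length(ratio))
  # unit-mean lognormal multipliers: empirical mean within 3 SE of 1
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("study structure matches the plate design", {
  cfg <- tiny_config(seed = 3)
  sim <- simulate_study(cfg)
  expect_length(sim$plates, nrow(sim$sheet) * length(cfg$ph_levels))
  p <- sim$plates[[1L]]
  roles <- table(vapply(p$traces, function(tr) tr$role, character(1)))
  expect_equal(as.integer(roles[c("digestion", "intrinsic", "substrate_only", "empty")]),
               c(14L * cfg$replicates, 1L, 14L, 2L))
  # exactly one intrinsic well per sample per plate, matching the plate's sample
  intr <- plate_traces(p, "intrinsic")[[1L]]
  dig <- plate_traces(p, "digestion")[[1L]]
  expect_equal(intr$sample_id, dig$sample_id)
  expect_equal(nrow(validate_layout(sim$plates, sim$sheet, cfg$panel)), 0L)
})

test_that("config validation rejects inconsistent setups", {
  expect_error(sim_config(cohorts = c(2, 2)), class = "protrace_config_error")
  expect_error(sim_config(cohorts = c(HC = 0L)), class = "protrace_config_error")
  expect_error(sim_config(high_background_fraction = 1.2), class = "protrace_config_error")
  expect_error(sim_config(timepoints_min = c(0, 5, 10)), class = "protrace_config_error")
  # effect matrix missing a cell
  em <- default_effect_matrix(c("HC", "CD"), load_substrate_panel(), 7.5)
  expect_error(sim_config(cohorts = c(HC = 2L, CD = 2L), ph_levels = 7.5,
                          effect_matrix = em[-1L, ]),
               class = "protrace_config_error")
})

test_that("inhibition experiment follows the paired-rate model", {
  cfg <- sim_config(cohorts = c(UC = 3L, CD = 3L), ph_levels = 7.5,
                    cv_log = 0.4, seed = 8)
  # complete inhibition: every inhibited rate is 0
  sim1 <- simulate_inhibition_experiment(cfg, furin_fraction = 1,
                                         inhibitor_efficiency = 1)
  expect_equal(sim1$truth$inhibited_rate, rep(0, 6))
  # zero efficiency: inhibited equals control
  sim0 <- simulate_inhibition_experiment(cfg, furin_fraction = 0.8,
                                         inhibitor_efficiency = 0)
  expect_equal(sim0$truth$inhibited_rate, sim0$truth$control_rate)
  # closed form: v_inh = v * (1 - f * e)
  sim2 <- simulate_inhibition_experiment(cfg, furin_fraction = 0.8,
                                         inhibitor_efficiency = 0.9)
  expect_equal(sim2$truth$inhibited_rate, sim2$truth$control_rate * (1 - 0.8 * 0.9))
  expect_equal(100 * (1 - 28 / 100), percent_inhibition(100, 100 * (1 - 0.8 * 0.9)))
  # paired wells share sample identity and differ in condition only
  p <- sim2$plates[[1L]]
  dig <- plate_traces(p, "digestion")
  conds <- vapply(dig, function(tr) tr$meta$condition, character(1))
  expect_setequal(unique(conds), c("control", "inhibitor"))
  expect_length(unique(vapply(dig, function(tr) tr$sample_id, character(1))), 1L)
  expect_error(simulate_inhibition_experiment(cfg, 1.2, 1),
               class = "protrace_input_error")
})

test_that("simulated studies serialize to the interchange formats", {
  cfg <- sim_config(cohorts = c(HC = 2L), panel = load_substrate_panel()[1:3, ],
                    ph_levels = 7.5, replicates = 1L, seed = 21)
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  runs <- read_kinetic_table(paths[["kinetics"]])
  expect_length(runs, 2L)
  expect_equal(read_sample_sheet(paths[["sheet"]]), sim$sheet)
})
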