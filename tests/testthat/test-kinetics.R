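make_plate <- function(empty_rfu, plate = "P1", extra = list()) {
  t <- seq(0, 75, 5)
  traces <- c(list(
    kinetic_trace(plate, "H12", t, rep(empty_rfu, 16)[1:16], role = "empty")),
    extra)
  plate_run(plate, traces)
}

test_that("normalization factors follow the empty-well arithmetic", {
  t <- seq(0, 75, 5)
  p <- make_plate(200)
  expect_equal(plate_normalization_factor(p, 100)$factor, 2)
  expect_equal(plate_normalization_factor(p, 200)$factor, 1)
  # mean over all reads of all empty wells: {90, 110, 100} vs reference 50
  p3 <- plate_run("P3", list(
    kinetic_trace("P3", "H10", t, rep(90, 16), role = "empty"),
    kinetic_trace("P3", "H11", t, rep(110, 16), role = "empty"),
    kinetic_trace("P3", "H12", t, rep(100, 16), role = "empty")))
  nf <- plate_normalization_factor(p3, 50)
  expect_equal(nf$factor, 2)
  expect_equal(nf$n_empty_wells, 3L)
  expect_error(plate_normalization_factor(p3, 0), class = "protrace_input_error")
  no_empty <- plate_run("P4", list(
    kinetic_trace("P4", "A1", t, 1 + t, role = "digestion",
                  sample_id = "S1", substrate_id = "X", ph = 7)))
  expect_error(plate_normalization_factor(no_empty, 100),
               class = "protrace_layout_error")
})

test_that("plate normalization divides every read and composes with scaling", {
  cfg <- tiny_config(seed = 41)
  sim <- simulate_study(cfg)
  p <- sim$plates[[2L]]
  expect_equal(normalize_plate(p, 1)$traces$A1$rfu, p$traces$A1$rfu)
  halved <- normalize_plate(p, 2)
  expect_equal(halved$traces$A1$rfu, p$traces$A1$rfu / 2)
  # normalize(scale(p, k), f * k) == normalize(p, f) over random plates
  for (k in c(0.5, 2, 10)) {
    f <- stats::runif(1, 0.5, 2)
    a <- normalize_plate(scale_plate(p, k), f * k)
    b <- normalize_plate(p, f)
    for (w in names(p$traces))
      expect_equal(a$traces[[w]]$rfu, b$traces[[w]]$rfu, tolerance = 1e-12)
  }
  expect_error(normalize_plate(p, 0), class = "protrace_input_error")
})

test_that("linear-phase detection handles the forced cases", {
  t <- seq(0, 75, 5)
  affine <- kinetic_trace("P1", "A1", t, 5 + 4 * t, role = "digestion",
                          sample_id = "S1", substrate_id = "X", ph = 7)
  win <- detect_linear_phase(affine)
  expect_equal(win$t_start, 0)
  expect_equal(win$t_end, 20)
  expect_false(win$low_activity)

  flat <- kinetic_trace("P1", "A2", t, rep(0, 16), role = "digestion",
                        sample_id = "S1", substrate_id = "X", ph = 7)
  wflat <- detect_linear_phase(flat)
  expect_true(wflat$low_activity)
  expect_equal(c(wflat$t_start, wflat$t_end), c(0, 20))

  few <- kinetic_trace("P1", "A3", c(0, 5, 10, 15), c(0, 1, 2, 3),
                       role = "digestion", sample_id = "S1",
                       substrate_id = "X", ph = 7)
  expect_error(detect_linear_phase(few, linear_phase_options(min_points = 5)),
               class = "protrace_input_error")
})

test_that("window detection matches the exhaustive brute-force search", {
  taus <- c(5, 10, 30, Inf)
  set.seed(77)
  for (rep in 1:60) {
    tau <- taus[(rep %% 4) + 1L]
    rate <- stats::runif(1, 1, 80)
    noise <- stats::runif(1, 0, 4)
    tr <- simulate_kinetic_trace(rate = rate, baseline = stats::runif(1, 0, 50),
                                 depletion_tau_min = tau, noise_sd = noise,
                                 seed = sample.int(1e6, 1))
    got <- detect_linear_phase(tr)
    want <- oracle_window(tr)
    expect_equal(got$t_start, want$t_start)
    expect_equal(got$t_end, want$t_end)
    expect_equal(got$low_activity, want$low_activity)
  }
})

test_that("slope fitting matches independent OLS and honors invariances", {
  t <- seq(0, 75, 5)
  lin <- kinetic_trace("P1", "A1", t, 10 + 3 * t, role = "digestion",
                       sample_id = "S1", substrate_id = "X", ph = 7)
  full <- list(t_start = 0, t_end = 75)
  f <- fit_slope(lin, full)
  expect_equal(f$rate_rfu_per_min, 3)
  expect_equal(f$r_squared, 1)

  const <- kinetic_trace("P1", "A2", t, rep(7, 16), role = "digestion",
                         sample_id = "S1", substrate_id = "X", ph = 7)
  expect_equal(fit_slope(const, full)$rate_rfu_per_min, 0)

  # noisy trace against lm() to 1e-10 relative
  tr <- simulate_kinetic_trace(rate = 12, baseline = 30, noise_sd = 5, seed = 9)
  got <- fit_slope(tr, full)
  want <- oracle_slope_lm(tr$time_min, tr$rfu)
  expect_equal(got$rate_rfu_per_min, want$slope, tolerance = 1e-10)
  expect_equal(got$stderr, want$stderr, tolerance = 1e-10)
  expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)

  # offset invariance: adding a constant leaves the slope unchanged
  for (c0 in c(-50, 13.7, 1000)) {
    shifted <- tr; shifted$rfu <- tr$rfu + c0
    expect_equal(fit_slope(shifted, full)$rate_rfu_per_min,
                 got$rate_rfu_per_min, tolerance = 1e-12)
  }
})

test_that("replicate aggregation follows the stated conventions", {
  expect_equal(aggregate_replicates(c(3, 3, 3)),
               data.frame(mean = 3, sd = 0, n = 3L))
  a <- aggregate_replicates(c(2, 4))
  expect_equal(a$mean, 3)
  expect_equal(a$sd, sqrt(2))
  single <- aggregate_replicates(5)
  expect_equal(single$mean, 5)
  expect_true(is.na(single$sd))
  expect_equal(single$n, 1L)
  expect_error(aggregate_replicates(numeric(0)), class = "protrace_input_error")
})

test_that("scaling a whole plate leaves normalized activity records unchanged", {
  cfg <- sim_config(cohorts = c(CD = 3L), panel = load_substrate_panel()[c(3, 11), ],
                    ph_levels = 7.5, replicates = 2L, seed = 61)
  sim <- simulate_study(cfg)
  fit0 <- fit_activity(sim$plates, sim$sheet, cfg$panel)
  for (k in c(0.5, 2, 10)) {
    plates_k <- sim$plates
    plates_k[[2L]] <- scale_plate(plates_k[[2L]], k)  # non-reference plate
    fit_k <- fit_activity(plates_k, sim$sheet, cfg$panel)
    expect_equal(fit_k$records$rate_rfu_per_min, fit0$records$rate_rfu_per_min,
                 tolerance = 1e-10)
  }
})
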