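rec_row <- function(sample, substrate, ph, rate, excluded = FALSE, cohort = "HC") {
  data.frame(sample_id = sample, cohort = cohort, substrate_id = substrate,
             ph = ph, rate_rfu_per_min = rate, rate_sd = 0, n_replicates = 3L,
             low_activity = FALSE, qc_excluded = excluded,
             stringsAsFactors = FALSE)
}

test_that("activity matrices assemble records cell by cell", {
  sheet <- data.frame(sample_id = c("S1", "S2"), cohort = c("HC", "CD"))
  recs <- rbind(rec_row("S1", "A", 7.5, 1), rec_row("S1", "B", 7.5, 2),
                rec_row("S2", "A", 7.5, 3), rec_row("S2", "B", 7.5, 4))
  m <- build_activity_matrix(recs, sheet)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["S1", "A@7.5"], 1)
  expect_equal(m["S2", "B@7.5"], 4)
  expect_equal(attr(m, "cohort"), c("HC", "CD"))

  # QC-excluded sample dropped under the policy flag, kept all-missing otherwise
  recs2 <- recs
  recs2$qc_excluded[recs2$sample_id == "S2"] <- TRUE
  expect_equal(rownames(build_activity_matrix(recs2, sheet, drop_excluded = TRUE)), "S1")
  kept <- build_activity_matrix(recs2, sheet, drop_excluded = FALSE)
  expect_true(all(is.na(kept["S2", ])))

  expect_error(build_activity_matrix(rbind(recs, recs[1L, ]), sheet),
               class = "protrace_integrity_error")
  expect_error(build_activity_matrix(recs, sheet[1L, ]),
               class = "protrace_join_error")
})

test_that("cohort means equal independent group-by means", {
  sheet <- data.frame(sample_id = c("S1", "S2", "S3"), cohort = c("HC", "HC", "CD"))
  recs <- rbind(rec_row("S1", "A", 7.5, 100), rec_row("S2", "A", 7.5, 300),
                rec_row("S3", "A", 7.5, 50, cohort = "CD"))
  prof <- cohort_mean_profile(build_activity_matrix(recs, sheet))
  expect_equal(prof$mean_rate[prof$cohort == "HC"], 200)
  expect_equal(prof$n[prof$cohort == "HC"], 2L)
  # cohort of one: means equal that sample's row
  expect_equal(prof$mean_rate[prof$cohort == "CD"], 50)

  # larger simulated cohort against aggregate()
  cfg <- sim_config(cohorts = c(HC = 4L, UC = 4L),
                    panel = load_substrate_panel()[c(1, 6, 12), ],
                    ph_levels = c(5.5, 7.5), replicates = 2L, seed = 19,
                    high_background_fraction = 0)
  sim <- simulate_study(cfg)
  fit <- fit_activity(sim$plates, sim$sheet, cfg$panel)
  prof2 <- cohort_mean_profile(coef(fit))
  byhand <- stats::aggregate(rate_rfu_per_min ~ cohort + substrate_id + ph,
                             data = fit$records[!fit$records$qc_excluded, ],
                             FUN = mean)
  for (i in seq_len(nrow(byhand))) {
    got <- prof2$mean_rate[prof2$cohort == byhand$cohort[i] &
                             prof2$substrate_id == byhand$substrate_id[i] &
                             prof2$ph == byhand$ph[i]]
    expect_equal(got, byhand$rate_rfu_per_min[i])
  }
})

fake_profile <- function(df) {
  df$n <- 1L
  class(df) <- c("cohort_profile", "data.frame")
  df
}

test_that("normalized contributions follow the clamp-and-divide rule", {
  panel <- load_substrate_panel()
  # one serine (RTKR) at 70, one cysteine (RSVL) at 30
  prof <- fake_profile(data.frame(cohort = "CD",
                                  substrate_id = c("RTKR-AMC", "RSVL-AMC"),
                                  ph = 7.5, mean_rate = c(70, 30)))
  ct <- normalized_contributions(prof, panel, "class")
  expect_equal(ct$fraction[ct$unit == "serine"], 0.7)
  expect_equal(ct$fraction[ct$unit == "cysteine"], 0.3)
  expect_equal(sum(ct$fraction), 1)

  # single substrate: fraction 1
  one <- fake_profile(data.frame(cohort = "CD", substrate_id = "RTKR-AMC",
                                 ph = 7.5, mean_rate = 42))
  expect_equal(normalized_contributions(one, panel, "substrate")$fraction, 1)

  # negative rates clamp to zero before dividing: {10, -5, 10} -> {.5, 0, .5}
  three <- fake_profile(data.frame(cohort = "CD",
                                   substrate_id = c("RTKR-AMC", "R-AMC", "RSVL-AMC"),
                                   ph = 7.5, mean_rate = c(10, -5, 10)))
  ct3 <- normalized_contributions(three, panel, "substrate")
  expect_equal(ct3$fraction[match(c("RTKR-AMC", "R-AMC", "RSVL-AMC"), ct3$unit)],
               c(0.5, 0, 0.5))

  # all-zero block: fractions undefined, flagged through the denominator
  zero <- fake_profile(data.frame(cohort = "HC", substrate_id = c("RTKR-AMC", "RSVL-AMC"),
                                  ph = 7.5, mean_rate = c(0, 0)))
  ctz <- normalized_contributions(zero, panel, "substrate")
  expect_true(all(is.na(ctz$fraction)))
  expect_equal(unique(ctz$denominator), 0)

  expect_error(normalized_contributions(
    fake_profile(data.frame(cohort = "CD", substrate_id = "NOPE", ph = 7, mean_rate = 1)),
    panel, "substrate"), class = "protrace_lookup_error")
})

test_that("contribution fractions are scale-invariant and internally consistent", {
  panel <- load_substrate_panel()
  set.seed(13)
  prof <- fake_profile(expand.grid(cohort = c("HC", "CD"),
                                   substrate_id = panel$substrate_id,
                                   ph = c(5.5, 7.5), stringsAsFactors = FALSE))
  prof$mean_rate <- stats::runif(nrow(prof), 0, 400)
  ct <- normalized_contributions(prof, panel, "substrate")
  # sums to 1 within each (cohort, ph) block
  sums <- tapply(ct$fraction, paste(ct$cohort, ct$ph), sum)
  expect_true(all(abs(sums - 1) <= 1e-12))
  expect_true(all(ct$fraction >= 0 & ct$fraction <= 1))

  # multiplying a block's rates by k leaves fractions unchanged
  prof_k <- prof
  sel <- prof_k$cohort == "CD" & prof_k$ph == 7.5
  prof_k$mean_rate[sel] <- prof_k$mean_rate[sel] * 7
  ct_k <- normalized_contributions(prof_k, panel, "substrate")
  expect_equal(ct_k$fraction, ct$fraction, tolerance = 1e-12)

  # class fractions equal sums of their member substrate fractions
  ct_class <- normalized_contributions(prof, panel, "class")
  for (block in unique(paste(ct$cohort, ct$ph))) {
    sub <- ct[paste(ct$cohort, ct$ph) == block, ]
    cls <- ct_class[paste(ct_class$cohort, ct_class$ph) == block, ]
    cys_members <- panel$substrate_id[panel$protease_class == "cysteine"]
    expect_equal(cls$fraction[cls$unit == "cysteine"],
                 sum(sub$fraction[sub$unit %in% cys_members]), tolerance = 1e-12)
  }

  # across-pH scope pools pH before normalizing
  ct_across <- normalized_contributions(prof, panel, "class", scope = "across_ph")
  expect_true(all(is.na(ct_across$ph)))
  pooled <- tapply(pmax(prof$mean_rate, 0),
                   list(prof$cohort,
                        panel$protease_class[match(prof$substrate_id, panel$substrate_id)]),
                   sum)
  expect_equal(ct_across$fraction[ct_across$cohort == "CD" & ct_across$unit == "cysteine"],
               pooled["CD", "cysteine"] / sum(pooled["CD", ]))
})
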