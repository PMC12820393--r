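# Two-plate fixture built in code: each plate has one digestion well, one
# intrinsic well, and one empty well on a shared 16-read grid.
make_fixture_frame <- function() {
  t <- seq(0, 75, by = 5)
  row <- function(pid, wid, sid, sub, role, rfu, rep = 1L)
    data.frame(plate_id = pid, well_id = wid, sample_id = sid, substrate_id = sub,
               ph = 7.5, replicate = rep, role = role, time_min = t, rfu = rfu,
               stringsAsFactors = FALSE)
  rbind(
    row("P1", "A1", "S1", "RTKR-AMC", "digestion", 100 + 3 * t),
    row("P1", "A2", "S1", NA, "intrinsic", rep(100, 16)),
    row("P1", "A3", NA, NA, "empty", rep(50, 16)),
    row("P2", "A1", "S2", "RTKR-AMC", "digestion", 110 + 5 * t),
    row("P2", "A2", "S2", NA, "intrinsic", rep(110, 16)),
    row("P2", "A3", NA, NA, "empty", rep(55, 16)))
}

test_that("long CSV parses into plate runs and survives row shuffling", {
  df <- make_fixture_frame()
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  runs <- read_kinetic_table(f)
  expect_length(runs, 2L)
  expect_named(runs, c("P1", "P2"))
  expect_length(runs$P1$traces, 3L)
  expect_equal(runs$P1$traces$A1$rfu, 100 + 3 * seq(0, 75, 5))
  expect_equal(runs$P2$traces$A1$role, "digestion")

  shuffled <- df[sample(nrow(df)), ]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(shuffled, f2, row.names = FALSE, na = "")
  expect_equal(read_kinetic_table(f2), runs)
})

test_that("write -> read -> write is a fixpoint", {
  df <- make_fixture_frame()
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  runs <- read_kinetic_table(f)
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_kinetic_table(runs, out1)
  write_kinetic_table(read_kinetic_table(out1), out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_equal(read_kinetic_table(out1), runs)
})

test_that("format errors name the problem", {
  df <- make_fixture_frame()
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, setdiff(names(df), "rfu")], f, row.names = FALSE, na = "")
  expect_error(read_kinetic_table(f), "rfu", class = "protrace_format_error")

  df2 <- make_fixture_frame()
  df2$role[1L] <- "mystery"
  utils::write.csv(df2, f, row.names = FALSE, na = "")
  expect_error(read_kinetic_table(f), "mystery", class = "protrace_format_error")

  # ragged grid within a plate: drop one read from one well
  df3 <- make_fixture_frame()
  df3 <- df3[!(df3$plate_id == "P1" & df3$well_id == "A3" & df3$time_min == 75), ]
  utils::write.csv(df3, f, row.names = FALSE, na = "")
  expect_error(read_kinetic_table(f), class = "protrace_layout_error")
})

test_that("an empty run list writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_kinetic_table(list(), f)
  lines <- readLines(f)
  expect_length(lines, 1L)
  expect_match(lines, "plate_id")
  expect_error(suppressWarnings(
    write_kinetic_table(list(), file.path(tempdir(), "no", "such", "dir.csv"))))
})

test_that("missed reads flag traces incomplete instead of being interpolated", {
  df <- make_fixture_frame()
  df$rfu[df$plate_id == "P1" & df$well_id == "A1" & df$time_min == 30] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  runs <- read_kinetic_table(f)
  expect_true(runs$P1$traces$A1$incomplete)
  expect_false(runs$P1$traces$A2$incomplete)
})

test_that("layout validation reports issues as data", {
  df <- make_fixture_frame()
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  runs <- read_kinetic_table(f)
  sheet <- data.frame(sample_id = c("S1", "S2"), cohort = c("HC", "CD"))
  panel <- load_substrate_panel()
  expect_equal(nrow(validate_layout(runs, sheet, panel)), 0L)

  # deleting a sample's intrinsic well yields exactly one issue
  runs2 <- runs
  runs2$P1$traces$A2 <- NULL
  issues <- validate_layout(runs2, sheet, panel)
  expect_equal(issues$issue, "missing_intrinsic")
  expect_equal(issues$sample_id, "S1")

  # unknown substrate
  runs3 <- runs
  runs3$P1$traces$A1$substrate_id <- "NOT-A-SUBSTRATE"
  issues3 <- validate_layout(runs3, sheet, panel)
  expect_true("unknown_substrate" %in% issues3$issue)

  # orphan sample id
  issues4 <- validate_layout(runs, sheet[sheet$sample_id != "S2", ], panel)
  expect_true(any(issues4$issue == "orphan_sample" & issues4$sample_id == "S2"))
})

test_that("sample sheets validate and round-trip", {
  sheet <- data.frame(sample_id = c("S1", "S2"), cohort = c("HC", "CD"),
                      phase = c("acute", "none"), notes = NA_character_)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(sheet, f)
  expect_equal(read_sample_sheet(f)$cohort, c("HC", "CD"))
  dup <- rbind(sheet, sheet[1L, ])
  expect_error(write_sample_sheet(dup, f), class = "protrace_format_error")
  # the same sample may recur in a different phase (follow-up sampling)
  follow <- rbind(sheet, data.frame(sample_id = "S1", cohort = "HC",
                                    phase = "remission", notes = NA_character_))
  expect_silent(write_sample_sheet(follow, f))
})
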