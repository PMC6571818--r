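t1 <- read_validation_table(leafscreen_extdata("table1_validation.csv"))
t2 <- read_validation_table(leafscreen_extdata("table2_validation.csv"))

test_that("MS/MS checklist cells parse into the three outcome types", {
  expect_identical(parse_msms_cell("no MS/MS", "X")$type, "no_msms")
  expect_identical(parse_msms_cell("no match", "X")$type, "no_match")
  bare <- parse_msms_cell("80%", "Coumarin")
  expect_identical(bare[c("type", "name")],
                   list(type = "hit", name = "Coumarin"))
  expect_equal(bare$score, 80)
  expect_equal(parse_msms_cell("96.8", "L-Aspartic acid")$score, 96.8)
  named <- parse_msms_cell("Benzyl Methacrylate, 61%", "Ethyl cinnamate")
  expect_identical(named$name, "Benzyl Methacrylate")
  expect_equal(named$score, 61)
  grp <- parse_msms_cell("3 or 4 methoxybenzaldehyde, 82%",
                         "3-Methoxybenzaldehyde")
  expect_identical(grp$name, "3 or 4 methoxybenzaldehyde")
  expect_error(parse_msms_cell("???", "X"), "cannot parse")
})

test_that("confirmation reproduces the packaged per-mode outcomes", {
  c1 <- confirm_toxic(t1)
  expect_setequal(c1$name, c("3-Methoxybenzaldehyde", "4-Methoxybenzaldehyde",
                             "Coumarin", "L-Glutamic acid",
                             "L-Phenylalanine"))
  c2 <- confirm_toxic(t2)
  expect_setequal(c2$name, c("Citric acid", "L-Aspartic acid",
                             "L-Glutamic acid", "Naringin"))
  # citric acid is confirmed despite the flagged peak shape
  expect_false(t2$good_peak_shape[t2$name == "Citric acid"])
  expect_true("Citric acid" %in% c2$name)
  # the name-inconsistent hit is rejected even though a score exists
  expect_false("Ethyl cinnamate" %in% c1$name)
  expect_equal(nrow(confirm_toxic(t1[0, ])), 0)
})

test_that("removing any required evidence un-confirms a confirmed row", {
  row <- t1[t1$name == "Coumarin", ]
  expect_equal(nrow(confirm_toxic(row)), 1)
  for (tweak in list(
    function(r) { r$not_in_blank <- FALSE; r },
    function(r) { r$above_noise <- FALSE; r },
    function(r) { r$isotopic_match <- "none"; r },
    function(r) { r$msms <- "no MS/MS"; r },
    function(r) { r$msms <- "no match"; r },
    function(r) { r$msms <- "60%"; r },
    function(r) { r$msms <- "Benzyl Methacrylate, 95%"; r }))
    expect_equal(nrow(confirm_toxic(tweak(row))), 0)
  # but a flagged shape alone does not
  soft <- row; soft$good_peak_shape <- FALSE
  expect_equal(nrow(confirm_toxic(soft)), 1)
})

test_that("polarity merging unions by normalized name with provenance", {
  merged <- merge_polarities(confirm_toxic(t1), confirm_toxic(t2))
  expect_equal(nrow(merged), 8)
  expect_identical(merged$modes[merged$name == "L-Glutamic acid"], "both")
  expect_equal(sum(merged$modes == "both"), 1)
  # the both-modes row keeps the higher-scoring mode's evidence
  expect_equal(merged$msms_score[merged$name == "L-Glutamic acid"], 99.5)
  x <- confirm_toxic(t1)
  expect_equal(nrow(merge_polarities(x, x[0, ])), nrow(x))
  expect_equal(nrow(merge_polarities(x, x)), nrow(x))
  expect_equal(nrow(merge_polarities(x[0, ], x[0, ])), 0)
})

test_that("validation tables round-trip through write/read unchanged", {
  for (tab in list(t1, t2)) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_validation_table(tab, path)
    expect_identical(read_validation_table(path), tab)
  }
})

test_that("render_report writes the per-mode and merged CSVs", {
  rep <- screening_report(t1, t2)
  dir <- withr::local_tempdir()
  files <- render_report(rep, dir)
  expect_identical(read_validation_table(files[["pos"]]), t1)
  expect_identical(read_validation_table(files[["neg"]]), t2)
  toxic <- utils::read.csv(files[["toxic"]], stringsAsFactors = FALSE)
  expect_equal(nrow(toxic), 8)
  empty <- screening_report(t1[0, ], t2[0, ])
  files0 <- render_report(empty, withr::local_tempdir())
  expect_equal(nrow(utils::read.csv(files0[["toxic"]])), 0)
})

test_that("the checklist records evidence for a spiked compound bundle", {
  sim <- simulate_run(
    list(spike_spec("Coumarin", "C9H6O2", "[M+H]+", 3, 6e5),
         spike_spec("Vanillin", "C8H8O3", "[M+H]+", 4.5, 4e5,
                    in_blank = TRUE),
         spike_spec("Benzaldehyde", "C7H6O", "[M+H]+", 2, 3e5,
                    has_msms = FALSE)),
    sim_params(duration = 6, seed = 5))
  lib <- sim$library
  row <- validate_candidate(list(name = "Coumarin", formula = "C9H6O2"),
                            sim$sample, sim$blank, lib)
  expect_true(row$not_in_blank && row$above_noise && row$good_peak_shape)
  expect_identical(row$isotopic_match, "[M+H]")
  hit <- parse_msms_cell(row$msms, row$name)
  expect_identical(hit$type, "hit")
  expect_identical(hit$name, "Coumarin")
  expect_gte(hit$score, 80)
  expect_equal(row$rt, 3, tolerance = 0.1)
  # blank contaminant fails step 1 only
  rowv <- validate_candidate(list(name = "Vanillin", formula = "C8H8O3"),
                             sim$sample, sim$blank, lib)
  expect_false(rowv$not_in_blank)
  expect_true(rowv$above_noise)
  # benzaldehyde ionizes but never got fragmented
  rowb <- validate_candidate(list(name = "Benzaldehyde", formula = "C7H6O"),
                             sim$sample, sim$blank, lib)
  expect_identical(rowb$msms, "no MS/MS")
  expect_error(validate_candidate(list(name = "X", formula = "C7H6O"),
                                  sim$sample, NULL), "blank")
})
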