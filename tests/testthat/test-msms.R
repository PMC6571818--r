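three_frag <- function(int = c(1, 1, 1), mz = c(81.07, 103.05, 147.04))
  msms_spectrum(148.06, mz, int, "pos")

test_that("normalization scales the base fragment to 1 and is idempotent", {
  s <- msms_spectrum(200, 150.1, 5, "pos")
  expect_equal(normalize_spectrum(s)$frag_intensity, 1)
  two <- msms_spectrum(300, c(100, 200), c(100, 200), "pos")
  expect_equal(normalize_spectrum(two)$frag_intensity, c(0.5, 1))
  expect_equal(normalize_spectrum(normalize_spectrum(two)),
               normalize_spectrum(two))
  zero <- msms_spectrum(300, c(100, 200), c(0, 0), "pos")
  expect_error(normalize_spectrum(zero), "zero")
  expect_error(msms_spectrum(100, 150, 1), "precursor")
})

test_that("similarity is 100 for self, 0 for disjoint, 66.7 for 2-of-3", {
  s <- three_frag()
  expect_equal(cosine_score(s, s), 100)
  other <- msms_spectrum(148.06, c(60.0, 70.0), c(1, 1), "pos")
  expect_equal(cosine_score(s, other), 0)
  # removing one of three equal-intensity fragments: (sum sqrt(qr))^2 /
  # (sum q sum r) = 2^2 / (2 * 3) = 66.7%
  two <- msms_spectrum(148.06, c(81.07, 103.05), c(1, 1), "pos")
  expect_equal(cosine_score(two, s), 200 / 3, tolerance = 1e-9)
})

test_that("similarity is symmetric and scale-invariant", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    a <- msms_spectrum(400, sort(stats::runif(n, 50, 390)),
                       stats::runif(n), "pos")
    m <- sample(3:8, 1)
    b <- msms_spectrum(400, sort(stats::runif(m, 50, 390)),
                       stats::runif(m), "pos")
    # give some shared fragments
    b$frag_mz[1:2] <- a$frag_mz[1:2] * (1 + 2e-6)
    b <- msms_spectrum(400, b$frag_mz, b$frag_intensity, "pos")
    expect_equal(cosine_score(a, b), cosine_score(b, a), tolerance = 1e-9)
    scaled <- msms_spectrum(400, a$frag_mz, a$frag_intensity * 37, "pos")
    expect_equal(cosine_score(scaled, b), cosine_score(a, b),
                 tolerance = 1e-9)
  }
})

test_that("deleting matched fragments never raises the score", {
  set.seed(42)
  for (i in 1:10) {
    n <- 6
    ref <- msms_spectrum(300, sort(stats::runif(n, 50, 290)),
                         stats::runif(n, 0.2, 1), "pos")
    full <- cosine_score(ref, ref)
    keep <- sort(sample(n, sample(2:(n - 1), 1)))
    sub <- msms_spectrum(300, ref$frag_mz[keep], ref$frag_intensity[keep],
                         "pos")
    expect_lte(cosine_score(sub, ref), full + 1e-9)
  }
})

test_that("library search honours precursor windows and isomer groups", {
  spikes <- default_spikes("pos")
  lib <- make_library(spikes)
  # self-search: every entry retrieves itself (or its isomer group) at 100
  for (e in lib) {
    hit <- library_search(e$spectrum, lib)
    expect_true(hit$hit)
    expect_equal(hit$score, 100, tolerance = 1e-9)
    ok_name <- if (is.na(e$isomer_group)) e$name else e$isomer_group
    expect_identical(hit$name, ok_name)
  }
  # the methoxybenzaldehyde pair reports its shared group label
  iso <- lib[[1]]
  expect_identical(library_search(iso$spectrum, lib)$name,
                   "3-Methoxybenzaldehyde or 4-Methoxybenzaldehyde")
  # 5% intensity noise keeps the score high but below perfect
  set.seed(43)
  q <- iso$spectrum
  q$frag_intensity <- q$frag_intensity * (1 + stats::rnorm(6, sd = 0.05))
  q <- msms_spectrum(q$precursor_mz, q$frag_mz, abs(q$frag_intensity), "pos")
  hit <- library_search(q, lib)
  expect_true(hit$hit && hit$score > 80 && hit$score < 100)
  # precursor far off every entry: no hit
  far <- msms_spectrum(iso$spectrum$precursor_mz * (1 + 5e-5),
                       iso$spectrum$frag_mz, iso$spectrum$frag_intensity,
                       "pos")
  expect_false(library_search(far, lib)$hit)
})

test_that("JSON and MSP library readers agree", {
  lib <- make_library(default_spikes("neg"))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_msms_library_json(lib, jpath)
  jlib <- read_msms_library_json(jpath)
  expect_equal(length(jlib), length(lib))
  expect_equal(jlib[[1]]$spectrum$frag_mz, lib[[1]]$spectrum$frag_mz)
  # write the same library as MSP text by hand
  mpath <- withr::local_tempfile(fileext = ".msp")
  lines <- unlist(lapply(lib, function(e) c(
    paste0("Name: ", e$name),
    paste0("Formula: ", format(e$formula)),
    paste0("PrecursorMZ: ", sprintf("%.6f", e$spectrum$precursor_mz)),
    "Polarity: Negative",
    if (!is.na(e$isomer_group)) paste0("IsomerGroup: ", e$isomer_group),
    paste0("Num Peaks: ", length(e$spectrum$frag_mz)),
    sprintf("%.6f %.6f", e$spectrum$frag_mz, e$spectrum$frag_intensity),
    "")))
  writeLines(lines, mpath)
  mlib <- read_msms_library_msp(mpath)
  expect_equal(length(mlib), length(lib))
  for (i in seq_along(lib)) {
    expect_identical(mlib[[i]]$name, lib[[i]]$name)
    expect_equal(mlib[[i]]$spectrum$frag_mz, lib[[i]]$spectrum$frag_mz,
                 tolerance = 1e-5)
    expect_equal(library_search(lib[[i]]$spectrum, mlib)$score, 100,
                 tolerance = 0.01)
  }
})
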