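test_that("single-carbon and coumarin patterns match the isotope constants", {
  it <- isotope_table()
  p <- theoretical_pattern(chem_formula(c(C = 1)))
  expect_equal(p$rel_abundance[1], 100)
  expect_equal(p$rel_abundance[2],
               it$C$abundance[2] / it$C$abundance[1] * 100,
               tolerance = 1e-9)  # ~1.08% of base
  pc <- theoretical_pattern("C9H6O2")
  expect_equal(pc$rel_abundance[2], 9.88, tolerance = 0.02)
  pw <- theoretical_pattern("H2O")
  expect_equal(max(pw$rel_abundance), 100)
})

test_that("isotopologue probabilities are conserved before normalization", {
  for (s in c("C9H6O2", "C5H9NO4", "C16H18N4O7S", "C27H32O14")) {
    counts <- unclass(parse_formula(s))
    res <- list(prob = 1, msum = 0)
    for (el in names(counts))
      if (counts[[el]] > 0)
        res <- leafscreen:::.dist_convolve(
          res, leafscreen:::.element_dist(el, counts[[el]], 40L), 40L)
    expect_equal(sum(res$prob), 1, tolerance = 1e-6)
  }
})

test_that("patterns agree with direct isotope-assignment enumeration", {
  for (s in c("H2O", "CH4", "C2H5NS", "C4H6O4", "C5H7S", "C3H3NO3")) {
    got <- theoretical_pattern(s, max_isotopologues = 4L, min_rel = 1e-6)
    want <- oracle_pattern(s)
    n <- min(nrow(got), 4L)
    expect_equal(got$mz[1:n], want$mz[1:n], tolerance = 1e-9, label = s)
    expect_equal(got$rel_abundance[1:n], want$rel_abundance[1:n],
                 tolerance = 1e-9, label = s)
  }
})

test_that("pattern of a sum equals the convolution of the patterns", {
  f1 <- "C3H4O2"; f2 <- "C2H5N"
  direct <- theoretical_pattern(formula_add(f1, f2), max_isotopologues = 4L,
                                min_rel = 1e-9)
  # manual convolution of the two oracle distributions
  a <- oracle_pattern(f1); b <- oracle_pattern(f2)
  conv <- rep(0, 4)
  for (i in seq_along(a$rel_abundance)) for (j in seq_along(b$rel_abundance)) {
    k <- i + j - 1
    if (k <= 4) conv[k] <- conv[k] + a$rel_abundance[i] * b$rel_abundance[j]
  }
  got <- direct$rel_abundance[1:4]
  expect_equal(got / got[1], conv / conv[1], tolerance = 1e-6)
})

test_that("adduct patterns shift by the charge carrier and adjust atoms", {
  p_ion <- theoretical_pattern("C9H6O2", "[M+H]+")
  expect_equal(p_ion$mz[1], 147.044054, tolerance = 1e-5)
  # water-loss ion of C9H8O3 coincides with [M+H]+ of C9H6O2 minus H2O+H
  p_loss <- theoretical_pattern("C9H8O3", "[M+H-H2O]+")
  expect_equal(p_loss$mz[1], p_ion$mz[1], tolerance = 1e-6)
  expect_identical(attr(p_ion, "adduct"), "[M+H]+")
})

test_that("pattern matching requires every major isotopologue", {
  pat <- theoretical_pattern("C9H6O2", "[M+H]+")
  full <- spectrum_from_pattern(pat)
  expect_true(match_pattern(full, pat)$matched)
  expect_identical(match_pattern(full, pat)$adduct, "[M+H]+")
  # drop the M+1 line of a C9 compound (9.9% >= the 5% requirement)
  truncated <- centroid_spectrum(1, full$mz[-2], full$intensity[-2], "pos")
  expect_false(match_pattern(truncated, pat)$matched)
  # distort the M+1 abundance beyond +/-30% relative
  bad <- full; bad$intensity[2] <- bad$intensity[2] * 1.6
  expect_false(match_pattern(bad, pat)$matched)
  # an unrelated spectrum has no base line at all
  other <- centroid_spectrum(1, c(120.1, 250.2), c(1e5, 2e4), "pos")
  expect_false(match_pattern(other, pat)$matched)
})

test_that("patterns serialize to CSV", {
  pat <- theoretical_pattern("C5H9NO4")
  path <- withr::local_tempfile(fileext = ".csv")
  write_pattern_csv(pat, path)
  back <- utils::read.csv(path)
  expect_equal(back$mz, pat$mz)
  expect_equal(back$rel_abundance, pat$rel_abundance)
})
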