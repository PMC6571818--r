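test_that("adduct arithmetic round-trips and uses electron-corrected deltas", {
  expect_equal(neutral_mass_from_ion(147.044056, "[M+H]+"), 146.036779,
               tolerance = 1e-5)
  expect_equal(neutral_mass_from_ion(145.029503, "[M-H]-"), 146.036779,
               tolerance = 1e-5)
  for (ad in names(default_adducts())) {
    m <- 321.0987
    expect_equal(neutral_mass_from_ion(ion_mz_from_neutral(m, ad), ad), m,
                 tolerance = 1e-9)
  }
  # proton, not hydrogen atom: the electron mass must be accounted
  expect_equal(ion_mz_from_neutral(0, "[M+H]+"), 1.0072765,
               tolerance = 1e-6)
  expect_error(neutral_mass_from_ion(150, "[M+K]+"), "registered")
})

test_that("constraint defaults carry the screening workflow's values", {
  cons <- screening_constraints()
  expect_equal(cons$tol_ppm, 3)
  expect_equal(cons$min_intensity, 20000)
  expect_equal(cons$c_range, c(1L, 90L))
  expect_equal(cons$h_range, c(1L, 190L))
  expect_equal(cons$o_range, c(0L, 18L))
  expect_equal(cons$n_range, c(0L, 5L))
  expect_equal(cons$s_range, c(0L, 1L))
  expect_equal(c(cons$hc_min, cons$hc_max), c(0.1, 3.5))
  expect_equal(c(cons$dbe_min, cons$dbe_max), c(0, 40))
  expect_equal(cons$sn_min, 3)
  expect_equal(cons$min_peak_area, 1000)
  expect_equal(c(cons$mz_min, cons$mz_max), c(100, 600))
  expect_identical(constraints_from_yaml(
    leafscreen_extdata("default_config.yaml")), cons)
})

test_that("enumeration finds the expected formulas and honours bounds", {
  hits <- enumerate_formulas(146.036779)
  expect_true("C9H6O2" %in% hits$formula)
  hits2 <- enumerate_formulas(147.053158)
  expect_true("C5H9NO4" %in% hits2$formula)
  expect_equal(nrow(enumerate_formulas(1.0)), 0)
})

test_that("assign_ion merges adduct hypotheses and enforces the window", {
  res <- assign_ion(147.04406, "pos")
  hit <- res[res$formula == "C9H6O2" & res$adduct == "[M+H]+", ]
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$ppm), 0.1)
  # the same ion as a water-loss hypothesis implies C9H8O3
  expect_true("C9H8O3" %in% res$formula[res$adduct == "[M+H-H2O]+"])
  expect_error(assign_ion(50, "pos"), "acquisition window")
})

test_that("enumeration is complete: recovers randomly drawn formulas", {
  set.seed(21)
  cons <- screening_constraints(c_range = c(1L, 30L))
  for (i in 1:40) {
    C <- sample(1:30, 1)
    H <- sample(max(1, ceiling(0.1 * C)):min(190, floor(3.5 * C)), 1)
    f <- chem_formula(c(C = C, H = H, N = sample(0:5, 1),
                        O = sample(0:18, 1), S = sample(0:1, 1)))
    if (dbe(f) < 0 || dbe(f) > 40) next
    hits <- enumerate_formulas(monoisotopic_mass(f), cons)
    expect_true(format(f) %in% hits$formula, label = format(f))
  }
})

test_that("every candidate satisfies the raw predicates (soundness)", {
  set.seed(22)
  cons <- screening_constraints()
  for (m in stats::runif(10, 100, 600)) {
    hits <- enumerate_formulas(m, cons)
    for (i in seq_len(nrow(hits))) {
      f <- parse_formula(hits$formula[i])
      expect_lte(abs(ppm_error(m, monoisotopic_mass(f))), cons$tol_ppm)
      expect_true(hc_ratio(f) >= cons$hc_min && hc_ratio(f) <= cons$hc_max)
      expect_true(dbe(f) >= cons$dbe_min && dbe(f) <= cons$dbe_max)
    }
  }
})

test_that("pruned enumeration equals the naive grid scan", {
  set.seed(23)
  cons <- screening_constraints(c_range = c(1L, 25L), h_range = c(1L, 60L))
  for (m in stats::runif(8, 100, 450)) {
    got <- sort(enumerate_formulas(m, cons)$formula)
    expect_identical(got, oracle_enumerate(m, cons))
  }
})

test_that("enlarging the tolerance never removes candidates", {
  set.seed(24)
  for (m in stats::runif(5, 100, 500)) {
    tight <- enumerate_formulas(m, screening_constraints(tol_ppm = 2))
    loose <- enumerate_formulas(m, screening_constraints(tol_ppm = 6))
    expect_true(all(tight$formula %in% loose$formula))
  }
})

test_that("candidates are ordered by |ppm|, then DBE, then Hill string", {
  res <- enumerate_formulas(300.1230,
                            screening_constraints(tol_ppm = 30))
  expect_gte(nrow(res), 2)
  o <- order(abs(res$ppm), res$dbe, res$formula)
  expect_identical(o, seq_len(nrow(res)))
})
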