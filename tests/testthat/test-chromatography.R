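# A small hand-built run: one compound eluting as a Gaussian at a fixed
# m/z plus a steady low-level contaminant centroid elsewhere.
two_ion_run <- function(apex = 1e5, rt0 = 5, sigma = 0.1, mz0 = 200.0,
                        label = "sample", noise_sd = 0) {
  times <- seq(0, 10, by = 0.05)
  spectra <- lapply(times, function(t) {
    i0 <- apex * exp(-(t - rt0)^2 / (2 * sigma^2))
    mz <- c(150.0, mz0); int <- c(500, i0)
    if (noise_sd > 0) int <- int + abs(stats::rnorm(2, sd = noise_sd))
    keep <- int > 1
    centroid_spectrum(t, mz[keep], int[keep], "pos")
  })
  lcms_run(spectra, label, "pos")
}

test_that("EIC extraction sums only in-window centroids", {
  run <- two_ion_run()
  tr <- build_eic(run, 300.0, 5)
  expect_true(all(tr$intensity == 0))
  tr2 <- build_eic(run, 200.0, 5)
  expect_equal(max(tr2$intensity), 1e5, tolerance = 1e-6)
  expect_equal(tr2$rt[which.max(tr2$intensity)], 5, tolerance = 0.051)
  # no intensity invented: EIC total bounded by the run's TIC
  tic <- sum(vapply(run$spectra, function(sp) sum(sp$intensity), numeric(1)))
  expect_lte(sum(tr2$intensity), tic)
})

test_that("peak detection applies the apex, S/N and area gates", {
  # flat zero trace
  expect_equal(nrow(detect_peaks(make_trace(seq(0, 10, 0.05),
                                            rep(0, 201)))), 0)
  # Gaussian over a noisy baseline (sigma 1e3): one peak, S/N = apex/noise
  set.seed(31)
  rt <- seq(0, 10, by = 0.05)
  y <- 1e5 * exp(-(rt - 5)^2 / (2 * 0.1^2)) + 1e4 +
    stats::rnorm(201, sd = 1e3)
  pk <- detect_peaks(make_trace(rt, y))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$sn, 1.1e5 / 1e3, tolerance = 0.2)
  expect_equal(pk$rt_apex, 5, tolerance = 0.051)
  # triangular peak with area ~500 is rejected by the area gate
  tri <- c(rep(0, 50), seq(0, 25000, length.out = 11),
           seq(25000, 0, length.out = 11)[-1], rep(0, 50))
  rt3 <- seq_along(tri) * 0.002
  expect_equal(nrow(detect_peaks(make_trace(rt3, tri))), 0)
  # same triangle stretched in time passes (area scales with width)
  rt4 <- seq_along(tri) * 0.01
  expect_equal(nrow(detect_peaks(make_trace(rt4, tri))), 1)
})

test_that("shape score separates Gaussian, noise and saw-tooth regions", {
  rt <- seq(0, 10, by = 0.05)
  y <- 2e5 * exp(-(rt - 5)^2 / (2 * 0.15^2))
  tr <- make_trace(rt, y)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1)
  expect_gte(pk$shape, 0.99)
  set.seed(32)
  noise <- make_trace(rt, abs(stats::rnorm(length(rt), sd = 1e4)))
  fake <- list(rt_left = 2, rt_right = 8, rt_apex = 5, height = 3e4)
  expect_lt(shape_score(fake, noise), 0.5)
  saw <- make_trace(rt, rep(c(1e4, 9e4), length.out = length(rt)))
  expect_lt(shape_score(fake, saw), 0.5)
  # degenerate single-point region
  expect_equal(shape_score(list(rt_left = 5, rt_right = 5.05, rt_apex = 5,
                                height = 1), tr), 0)
})

test_that("blank comparison matches peaks by apex retention time", {
  sample_run <- two_ion_run()
  pk <- detect_peaks(build_eic(sample_run, 200.0, 5))[1, ]
  empty_blank <- two_ion_run(apex = 0.5, label = "blank")
  expect_false(present_in_blank(pk, empty_blank, 200.0))
  same_blank <- two_ion_run(label = "blank")
  expect_true(present_in_blank(pk, same_blank, 200.0))
  shifted_blank <- two_ion_run(rt0 = 7, label = "blank")
  expect_false(present_in_blank(pk, shifted_blank, 200.0, rt_tol_min = 0.2))
})

test_that("appending all-zero spectra does not change detected peaks", {
  run <- two_ion_run(noise_sd = 800)
  tr <- build_eic(run, 200.0, 5)
  before <- detect_peaks(tr)
  padded <- make_trace(c(tr$rt, seq(10.05, 12, by = 0.05)),
                       c(tr$intensity, rep(0, 40)),
                       tr$target_mz, tr$tol_ppm)
  after <- detect_peaks(padded)
  expect_equal(before, after)
})

test_that("spiked compounds are recovered exactly once, noise-only never", {
  for (seed in 1:20) {
    sim <- simulate_run(
      list(spike_spec("Coumarin", "C9H6O2", "[M+H]+", 3, 5e5, sigma = 0.08)),
      sim_params(duration = 6, seed = seed))
    mz0 <- sim$truth$mz[1]
    pk <- detect_peaks(build_eic(sim$sample, mz0, 3))
    expect_equal(nrow(pk), 1)
    expect_equal(pk$rt_apex, 3, tolerance = 0.1)
    # a spike-free window stays peak-free
    off <- detect_peaks(build_eic(sim$sample, 333.2222, 3))
    expect_equal(nrow(off), 0)
  }
})

test_that("runs survive the JSON round-trip bit-identically", {
  sim <- simulate_run(
    list(spike_spec("Coumarin", "C9H6O2", "[M+H]+", 2, 3e5)),
    sim_params(duration = 4, seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_run_json(sim$sample, path)
  back <- read_run_json(path)
  expect_equal(back, sim$sample, tolerance = 1e-12)
})
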