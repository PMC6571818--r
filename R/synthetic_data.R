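# Deterministic synthetic LC-MS runs with known ground truth: Gaussian
# elution profiles of spiked compounds (with full isotopologue
# envelopes and uniform +/-2 ppm mass error), Poisson noise centroids,
# top-5 data-dependent MS/MS with dynamic exclusion, and a paired blank
# run carrying only the designated contaminant spikes.

# Run expr under a fixed RNG seed without disturbing the caller's
# random stream.
.with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit string hash (for per-compound spectrum seeds).
.string_seed <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Define a spiked compound for run simulation
#'
#' @param name Compound name.
#' @param formula Neutral formula.
#' @param adduct Registered adduct name the compound ionizes as.
#' @param rt Apex retention time in minutes (inside the run duration).
#' @param apex Apex intensity in counts (> 0).
#' @param sigma Chromatographic peak width (Gaussian sigma) in minutes.
#' @param in_blank Also spike the compound into the blank run
#'   (a contaminant).
#' @param has_msms Attach data-dependent MS/MS spectra when the ion is
#'   among the tallest precursors.
#' @return A `spike_spec` object.
#' @export
spike_spec <- function(name, formula, adduct = "[M+H]+", rt, apex,
                       sigma = 0.08, in_blank = FALSE, has_msms = TRUE) {
  stopifnot(apex > 0, sigma > 0)
  structure(list(name = name, formula = .as_formula(formula),
                 adduct = adduct, rt = rt, apex = apex, sigma = sigma,
                 in_blank = in_blank, has_msms = has_msms),
            class = "spike_spec")
}

#' Simulation parameters
#'
#' Defaults emulate the screening acquisition at desk scale: 30 min
#' runs (no peak elutes later), full-scan centroid spectra over m/z
#' 100-600, and top-5 data-dependent MS/MS.  The scan interval and
#' noise model are this package's choices: 0.03 min between full
#' scans, Poisson(40) noise centroids per scan at uniform m/z with
#' exponential intensities (mean 2000, far below the 20,000 intensity
#' floor), and uniform +/-2 ppm mass error on every true centroid so
#' no ground-truth ion can leak out of the 3 ppm gate.
#'
#' @param duration Run length in minutes.
#' @param scan_interval Time between full scans in minutes.
#' @param mz_range Acquisition m/z window (Da).
#' @param noise_rate Expected noise centroids per scan (Poisson).
#' @param noise_mean Mean noise centroid intensity (exponential).
#' @param mass_error_ppm Half-width of the uniform mass error (ppm).
#' @param dda_top Number of tallest precursors fragmented per scan.
#' @param dda_min_intensity Minimum precursor intensity to trigger
#'   MS/MS.
#' @param dda_exclusion Dynamic exclusion window in minutes.
#' @param msms_noise_rel Relative intensity noise on MS/MS fragments.
#' @param seed Integer seed; fixed seed implies bit-identical runs.
#' @param polarity `"pos"` or `"neg"`.
#' @return A `sim_params` list.
#' @export
sim_params <- function(duration = 30, scan_interval = 0.03,
                       mz_range = c(100, 600), noise_rate = 40,
                       noise_mean = 2000, mass_error_ppm = 2,
                       dda_top = 5, dda_min_intensity = 10000,
                       dda_exclusion = 0.5, msms_noise_rel = 0.05,
                       seed = 1L, polarity = "pos") {
  structure(list(duration = duration, scan_interval = scan_interval,
                 mz_range = mz_range, noise_rate = noise_rate,
                 noise_mean = noise_mean, mass_error_ppm = mass_error_ppm,
                 dda_top = dda_top, dda_min_intensity = dda_min_intensity,
                 dda_exclusion = dda_exclusion,
                 msms_noise_rel = msms_noise_rel,
                 seed = as.integer(seed),
                 polarity = .polarity_label(polarity)),
            class = "sim_params")
}

#' Build a deterministic MS/MS library for a set of spikes
#'
#' Each compound gets a pseudo-fragment spectrum generated from a
#' seeded hash of its name (six fragments below the precursor, with
#' reproducible intensities).  Spikes sharing a formula are treated as
#' an isomer group: they share one spectrum and a group label of the
#' form `"A or B"`, so a library search reports the group rather than
#' an arbitrary member.
#'
#' @param spikes List of [spike_spec()] objects.
#' @param n_fragments Fragments per spectrum.
#' @param adducts Adduct registry.
#' @return List of [library_entry()] objects.
#' @export
make_library <- function(spikes, n_fragments = 6L,
                         adducts = default_adducts()) {
  if (!length(spikes)) return(list())
  fmls <- vapply(spikes, function(s) format(s$formula), character(1))
  groups <- list()
  for (fml in unique(fmls)) {
    members <- vapply(spikes[fmls == fml], `[[`, character(1), "name")
    members <- unique(members)
    if (length(members) > 1)
      groups[[paste(sort(members), collapse = " or ")]] <- sort(members)
  }
  lapply(spikes, function(s) {
    grp <- NA_character_
    for (label in names(groups))
      if (s$name %in% groups[[label]]) grp <- label
    key <- if (is.na(grp)) s$name else grp
    precursor <- monoisotopic_mass(s$formula) +
      .find_adduct(s$adduct, adducts)$delta
    sp <- .with_local_seed(.string_seed(key), {
      mzs <- sort(stats::runif(n_fragments, 50, precursor - 2))
      ints <- stats::runif(n_fragments, 0.2, 1)
      msms_spectrum(precursor, mzs, ints,
                    if (.find_adduct(s$adduct, adducts)$polarity > 0)
                      "pos" else "neg")
    })
    library_entry(s$name, s$formula, sp, grp)
  })
}

#' Isomer groups implied by a spectral library
#'
#' @param library List of [library_entry()] objects.
#' @return Named list (group label -> member names) usable as the
#'   `isomer_groups` argument of [confirm_toxic()].
#' @export
library_isomer_groups <- function(library) {
  grp <- vapply(library, `[[`, character(1), "isomer_group")
  out <- list()
  for (g in unique(grp[!is.na(grp)]))
    out[[g]] <- vapply(library[which(grp == g)], `[[`, character(1), "name")
  out
}

#' Simulate a paired sample/blank LC-MS run with known ground truth
#'
#' The sample run carries every spike; the blank run carries only the
#' `in_blank` contaminant spikes.  Both runs share the noise model
#' (independent draws).  Each spike contributes its full isotopologue
#' envelope (from [theoretical_pattern()]) scaled by a Gaussian elution
#' profile; every true centroid receives uniform mass error.  In the
#' sample run, the `dda_top` tallest centroids of each scan above
#' `dda_min_intensity` trigger MS/MS (with dynamic exclusion): spikes
#' with `has_msms` yield their library spectrum perturbed by intensity
#' noise and fragment m/z jitter, other precursors yield unmatchable
#' noise spectra.
#'
#' @param spikes List of [spike_spec()] objects (ion m/z must fall
#'   inside the acquisition window).
#' @param params A [sim_params()] list.
#' @param library Optional library from [make_library()] (built
#'   internally when NULL) used as the fragmentation ground truth.
#' @param adducts Adduct registry.
#' @return A list: `sample` and `blank` [lcms_run()]s, `truth` (a
#'   data.frame with one row per spike: name, formula, adduct, ion mz,
#'   rt, apex, in_blank, has_msms, expect_confirmed), and `library`.
#' @export
simulate_run <- function(spikes, params = sim_params(), library = NULL,
                         adducts = default_adducts()) {
  pol <- .polarity_sign(params$polarity)
  for (s in spikes) {
    ad <- .find_adduct(s$adduct, adducts)
    if (ad$polarity != pol)
      stop("spike ", s$name, " adduct polarity differs from the run's")
    mz <- monoisotopic_mass(s$formula) + ad$delta
    if (mz < params$mz_range[1] || mz > params$mz_range[2])
      stop(sprintf("spike %s ion m/z %.4f outside the acquisition window",
                   s$name, mz))
    if (s$rt < 0 || s$rt > params$duration)
      stop("spike ", s$name, " elutes outside the run duration")
  }
  if (is.null(library)) library <- make_library(spikes, adducts = adducts)
  lines <- lapply(spikes, function(s) {
    pat <- theoretical_pattern(s$formula, s$adduct, max_isotopologues = 4L,
                               min_rel = 0.1, adducts = adducts)
    list(mz = pat$mz, rel = pat$rel_abundance / 100,
         base_mz = pat$mz[which.max(pat$rel_abundance)])
  })
  lib_by_name <- stats::setNames(library,
                                 vapply(library, `[[`, character(1), "name"))
  .with_local_seed(params$seed, {
    sample <- .simulate_one(spikes, lines, lib_by_name, params,
                            blank = FALSE)
    blank <- .simulate_one(spikes, lines, lib_by_name, params,
                           blank = TRUE)
  })
  truth <- data.frame(
    name = vapply(spikes, `[[`, character(1), "name"),
    formula = vapply(spikes, function(s) format(s$formula), character(1)),
    adduct = vapply(spikes, `[[`, character(1), "adduct"),
    mz = vapply(seq_along(spikes), function(i) lines[[i]]$base_mz,
                numeric(1)),
    rt = vapply(spikes, `[[`, numeric(1), "rt"),
    apex = vapply(spikes, `[[`, numeric(1), "apex"),
    in_blank = vapply(spikes, `[[`, logical(1), "in_blank"),
    has_msms = vapply(spikes, `[[`, logical(1), "has_msms"),
    stringsAsFactors = FALSE)
  truth$expect_confirmed <- !truth$in_blank & truth$has_msms &
    truth$apex >= 20000
  list(sample = sample, blank = blank, truth = truth, library = library)
}

# Generate one run (sample or blank).  Consumes the active RNG stream.
.simulate_one <- function(spikes, lines, lib_by_name, params, blank) {
  active <- if (blank) which(vapply(spikes, `[[`, logical(1), "in_blank"))
  else seq_along(spikes)
  times <- seq(0, params$duration, by = params$scan_interval)
  spectra <- vector("list", length(times))
  msms <- list()
  excl_mz <- numeric(0); excl_until <- numeric(0)
  for (k in seq_along(times)) {
    t <- times[k]
    n_noise <- stats::rpois(1, params$noise_rate)
    mz <- stats::runif(n_noise, params$mz_range[1], params$mz_range[2])
    int <- stats::rexp(n_noise, 1 / params$noise_mean)
    origin <- rep(0L, n_noise)  # 0 = noise, else spike index
    for (i in active) {
      s <- spikes[[i]]
      elut <- s$apex * exp(-(t - s$rt)^2 / (2 * s$sigma^2))
      if (elut < 20) next
      li <- lines[[i]]
      keep <- li$rel * elut >= 1
      if (!any(keep)) next
      err <- stats::runif(sum(keep), -params$mass_error_ppm,
                          params$mass_error_ppm) * 1e-6
      mz <- c(mz, li$mz[keep] * (1 + err))
      int <- c(int, elut * li$rel[keep])
      origin <- c(origin, ifelse(li$mz[keep] == li$base_mz, i, -1L))
    }
    o <- order(mz)
    mz <- mz[o]; int <- int[o]; origin <- origin[o]
    while (length(mz) > 1 && any(diff(mz) <= 0)) {
      j <- which(diff(mz) <= 0) + 1L
      mz[j] <- mz[j] + 1e-7
      o <- order(mz); mz <- mz[o]; int <- int[o]; origin <- origin[o]
    }
    spectra[[k]] <- centroid_spectrum(t, mz, int, params$polarity)
    if (blank || !length(mz)) next
    # data-dependent MS/MS on the tallest precursors
    live <- excl_until > t
    excl_mz <- excl_mz[live]; excl_until <- excl_until[live]
    tall <- order(int, decreasing = TRUE)
    tall <- tall[int[tall] >= params$dda_min_intensity]
    tall <- utils::head(tall, params$dda_top)
    for (j in tall) {
      if (length(excl_mz) &&
          any(abs(mz[j] - excl_mz) / excl_mz * 1e6 <= 10)) next
      excl_mz <- c(excl_mz, mz[j])
      excl_until <- c(excl_until, t + params$dda_exclusion)
      q <- .dda_spectrum(mz[j], origin[j], spikes, lib_by_name, params)
      if (is.null(q)) next
      attr(q, "rt") <- t
      msms[[length(msms) + 1L]] <- q
    }
  }
  lcms_run(spectra, if (blank) "blank" else "sample", params$polarity, msms)
}

# Query spectrum for one fragmented precursor; NULL when the precursor
# is a spike whose MS/MS acquisition is disabled.
.dda_spectrum <- function(prec_mz, origin, spikes, lib_by_name, params) {
  if (origin > 0L) {
    s <- spikes[[origin]]
    if (!s$has_msms) return(NULL)
    ref <- lib_by_name[[s$name]]$spectrum
    ints <- ref$frag_intensity *
      pmax(1 + stats::rnorm(length(ref$frag_intensity),
                            sd = params$msms_noise_rel), 0.05)
    jitter <- stats::runif(length(ref$frag_mz), -3e-6, 3e-6)
    msms_spectrum(prec_mz, ref$frag_mz * (1 + jitter), ints,
                  params$polarity)
  } else {
    nfrag <- 5L
    msms_spectrum(prec_mz, sort(stats::runif(nfrag, 50, prec_mz - 2)),
                  stats::runif(nfrag, 0.1, 1), params$polarity)
  }
}

#' Standard spike sets for the two ionization modes
#'
#' The packaged study conditions: the confirmed toxic compounds of the
#' leaf-concentrate screen, spiked at their reported retention times,
#' with salicylic acid as the blank-contaminant control in negative
#' mode (it elutes in both runs and must be rejected at checklist
#' step 1).
#'
#' @param polarity `"pos"` or `"neg"`.
#' @return List of [spike_spec()] objects.
#' @export
default_spikes <- function(polarity = "pos") {
  if (.polarity_sign(polarity) > 0)
    list(
      spike_spec("3-Methoxybenzaldehyde", "C8H8O2", "[M+H]+", 11.49, 6e5),
      spike_spec("4-Methoxybenzaldehyde", "C8H8O2", "[M+H]+", 12.99, 5e5),
      spike_spec("Coumarin", "C9H6O2", "[M+H]+", 17.63, 8e5),
      spike_spec("L-Glutamic acid", "C5H9NO4", "[M+H]+", 1.74, 1e6),
      spike_spec("L-Phenylalanine", "C9H11NO2", "[M+H]+", 4.02, 9e5))
  else
    list(
      spike_spec("Citric acid", "C6H8O7", "[M-H]-", 2.46, 7e5),
      spike_spec("L-Aspartic acid", "C4H7NO4", "[M-H]-", 1.73, 8e5),
      spike_spec("L-Glutamic acid", "C5H9NO4", "[M-H]-", 1.73, 9e5),
      spike_spec("Naringin", "C27H32O14", "[M-H]-", 22.93, 6e5),
      spike_spec("Salicylic acid", "C7H6O3", "[M-H]-", 21.71, 4e5,
                 in_blank = TRUE))
}

#' Simulate and screen both polarities end to end
#'
#' Convenience driver: simulates paired sample/blank runs for each
#' polarity from [default_spikes()] (or supplied spike sets), screens
#' them against the packaged toxin table with the simulation's own
#' MS/MS library, and assembles the merged report.
#'
#' @param seed Integer seed for both simulations.
#' @param constraints A [screening_constraints()] list.
#' @param pos_spikes,neg_spikes Spike sets per polarity.
#' @return A list: `report` (a [screening_report()]), `truth_pos`,
#'   `truth_neg` (simulation truth tables), and `expected` (the
#'   merged expected-confirmed compound names).
#' @export
screen_synthetic <- function(seed = 1L,
                             constraints = screening_constraints(),
                             pos_spikes = default_spikes("pos"),
                             neg_spikes = default_spikes("neg")) {
  toxdb <- read_toxin_db(leafscreen_extdata("toxins.csv"))
  sim_p <- simulate_run(pos_spikes, sim_params(seed = seed,
                                               polarity = "pos"))
  sim_n <- simulate_run(neg_spikes, sim_params(seed = seed + 1L,
                                               polarity = "neg"))
  groups <- c(library_isomer_groups(sim_p$library),
              library_isomer_groups(sim_n$library))
  rows_p <- screen_run(sim_p$sample, sim_p$blank, toxdb, sim_p$library,
                       constraints)
  rows_n <- screen_run(sim_n$sample, sim_n$blank, toxdb, sim_n$library,
                       constraints)
  report <- screening_report(rows_p, rows_n, isomer_groups = groups)
  expected <- merge_polarities(
    sim_p$truth$name[sim_p$truth$expect_confirmed],
    sim_n$truth$name[sim_n$truth$expect_confirmed])
  list(report = report, truth_pos = sim_p$truth, truth_neg = sim_n$truth,
       expected = expected)
}
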