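# Theoretical isotopologue patterns by polynomial expansion of the
# per-element isotope distributions, aggregated at nominal (unit) mass
# resolution, and pattern matching against measured centroid spectra.
# At 120K resolving power the CHNOS fine structure below m/z ~400 is
# unresolved, so aggregated patterns are what the instrument sees.

# Single-atom distribution for one element on the neutron-shift grid:
# prob[k+1] = P(shift k), msum[k+1] = E[mass * 1{shift k}].
.atom_dist <- function(el) {
  iso <- .ISOTOPE_TABLE[[el]]
  shift <- as.integer(round(iso$mass - iso$mass[1]))
  n <- max(shift) + 1L
  prob <- numeric(n); msum <- numeric(n)
  for (i in seq_along(shift)) {
    prob[shift[i] + 1L] <- prob[shift[i] + 1L] + iso$abundance[i]
    msum[shift[i] + 1L] <- msum[shift[i] + 1L] + iso$abundance[i] * iso$mass[i]
  }
  list(prob = prob, msum = msum)
}

# Convolve two (prob, msum) distributions; truncate at maxlen bins.
.dist_convolve <- function(a, b, maxlen) {
  la <- length(a$prob); lb <- length(b$prob)
  n <- min(la + lb - 1L, maxlen)
  prob <- numeric(n); msum <- numeric(n)
  for (i in seq_len(la)) {
    jmax <- min(lb, n - i + 1L)
    if (jmax < 1L) break
    j <- seq_len(jmax)
    k <- i + j - 1L
    prob[k] <- prob[k] + a$prob[i] * b$prob[j]
    msum[k] <- msum[k] + a$msum[i] * b$prob[j] + a$prob[i] * b$msum[j]
  }
  list(prob = prob, msum = msum)
}

# Distribution of n atoms of one element, by binary exponentiation.
.element_dist <- function(el, n, maxlen) {
  res <- list(prob = 1, msum = 0)
  base <- .atom_dist(el)
  while (n > 0L) {
    if (n %% 2L == 1L) res <- .dist_convolve(res, base, maxlen)
    base <- .dist_convolve(base, base, maxlen)
    n <- n %/% 2L
  }
  res
}

#' Theoretical isotopologue pattern of a formula
#'
#' Computes the aggregated (nominal-mass-binned) isotopologue
#' distribution of a formula, optionally as a specific adduct ion, by
#' convolving the per-element isotope distributions.  Abundances are
#' normalized so the base (most abundant) isotopologue is exactly 100;
#' each bin's m/z is the abundance-weighted centroid of the
#' isotopologues it aggregates.
#'
#' @param f A formula (any representation accepted by [chem_formula()]).
#' @param adduct Optional `adduct_spec` or registered adduct name; when
#'   given, the pattern is computed for the full ion composition (atoms
#'   gained/lost by the adduct included) and m/z values are ion m/z.
#' @param max_isotopologues Number of isotopologue bins retained
#'   (>= 1).
#' @param min_rel Drop bins below this relative abundance (% of base).
#' @param adducts Adduct registry for name lookup.
#' @return An `isotope_pattern` data.frame with columns `mz` and
#'   `rel_abundance` (sorted by m/z, base = 100), with attribute
#'   `adduct` (label or NA).
#' @examples
#' theoretical_pattern("C9H6O2")           # M+1 about 9.8% of M
#' theoretical_pattern("C9H6O2", "[M+H]+")
#' @export
theoretical_pattern <- function(f, adduct = NULL, max_isotopologues = 6L,
                                min_rel = 0.01,
                                adducts = default_adducts()) {
  stopifnot(max_isotopologues >= 1L)
  f <- .as_formula(f)
  label <- NA_character_
  extra <- 0
  counts <- unclass(f)
  if (!is.null(adduct)) {
    ad <- .find_adduct(adduct, adducts)
    label <- ad$name
    extra <- ad$extra_mass
    counts <- .formula_combine_raw(f, ad$formula_shift)
    if (any(counts < 0))
      stop("adduct ", ad$name, " removes atoms the formula lacks")
  }
  # convolve with generous bin head-room, truncate at the end
  maxlen <- max_isotopologues + 4L
  res <- list(prob = 1, msum = 0)
  for (el in .ELEMENTS)
    if (counts[[el]] > 0L)
      res <- .dist_convolve(res, .element_dist(el, counts[[el]], maxlen),
                            maxlen)
  keep <- res$prob > 0
  prob <- res$prob[keep]
  mz <- res$msum[keep] / prob + extra
  nk <- min(length(prob), max_isotopologues)
  prob <- prob[seq_len(nk)]; mz <- mz[seq_len(nk)]
  rel <- prob / max(prob) * 100
  ok <- rel >= min_rel
  out <- data.frame(mz = mz[ok], rel_abundance = rel[ok])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("isotope_pattern", "data.frame"), adduct = label)
}

#' Match a theoretical isotope pattern against a measured spectrum
#'
#' The pattern matches when every theoretical isotopologue whose
#' abundance is at least `min_rel_required` % of the base has a
#' measured centroid within `mz_tol_ppm` whose abundance relative to
#' the measured base centroid agrees within `abundance_tol_rel`
#' (relative, i.e. 0.3 = +/-30%).
#'
#' @param measured A [centroid_spectrum()].
#' @param pattern An [theoretical_pattern()] result.
#' @param mz_tol_ppm m/z tolerance for locating each isotopologue.
#' @param abundance_tol_rel Relative abundance tolerance.
#' @param min_rel_required Only isotopologues at or above this % of base
#'   must be observed.
#' @return A list with `matched` (logical) and `adduct` (the pattern's
#'   adduct label, or NA), mirroring checklist cells like
#'   `"[M+H] match"`.
#' @export
match_pattern <- function(measured, pattern, mz_tol_ppm = 5,
                          abundance_tol_rel = 0.3, min_rel_required = 5) {
  stopifnot(nrow(pattern) >= 1L)
  label <- attr(pattern, "adduct")
  base_i <- which.max(pattern$rel_abundance)
  base_meas <- .nearest_centroid(measured, pattern$mz[base_i], mz_tol_ppm)
  if (is.na(base_meas) || measured$intensity[base_meas] <= 0)
    return(list(matched = FALSE, adduct = label))
  base_int <- measured$intensity[base_meas]
  need <- which(pattern$rel_abundance >= min_rel_required)
  for (i in need) {
    j <- .nearest_centroid(measured, pattern$mz[i], mz_tol_ppm)
    if (is.na(j)) return(list(matched = FALSE, adduct = label))
    rel_meas <- measured$intensity[j] / base_int * 100
    if (abs(rel_meas - pattern$rel_abundance[i]) >
        abundance_tol_rel * pattern$rel_abundance[i])
      return(list(matched = FALSE, adduct = label))
  }
  list(matched = TRUE, adduct = label)
}

# Index of the most intense centroid within tol_ppm of mz, or NA.
.nearest_centroid <- function(spectrum, mz, tol_ppm) {
  half <- mz * tol_ppm * 1e-6
  j <- which(spectrum$mz >= mz - half & spectrum$mz <= mz + half)
  if (!length(j)) return(NA_integer_)
  j[which.max(spectrum$intensity[j])]
}

#' Write an isotope pattern to CSV
#'
#' @param pattern An [theoretical_pattern()] result.
#' @param path Output CSV path (columns `mz`, `rel_abundance`).
#' @return `path`, invisibly.
#' @export
write_pattern_csv <- function(pattern, path) {
  utils::write.csv(as.data.frame(pattern)[c("mz", "rel_abundance")],
                   path, row.names = FALSE)
  invisible(path)
}
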