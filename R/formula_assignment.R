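# Adduct arithmetic and exhaustive CHNOS formula enumeration for an
# observed ion m/z under the screening constraint set (mass tolerance,
# element ranges, H/C and DBE windows).

#' Define an adduct
#'
#' An adduct maps a neutral monoisotopic mass M to a singly charged ion
#' m/z via a fixed mass delta.  The delta accounts for the electron:
#' e.g. \[M+H\]+ adds a proton (1.00727646688 Da), not a hydrogen atom.
#' `formula_shift` records the CHNOS atoms gained or lost by the ion
#' relative to M (used for isotopologue patterns); `extra_mass` is the
#' non-CHNOS remainder (charge carrier and electron), so that
#' `delta == mass(formula_shift) + extra_mass`.
#'
#' @param name Adduct label, e.g. `"[M+H]+"`.
#' @param polarity `+1` or `-1`.
#' @param delta Mass delta in Da applied to the neutral mass.
#' @param formula_shift Named integer vector of element count changes.
#' @param extra_mass Non-CHNOS mass remainder in Da.
#' @return An `adduct_spec` object.
#' @export
adduct_spec <- function(name, polarity, delta, formula_shift = integer(),
                        extra_mass = delta) {
  stopifnot(polarity %in% c(1L, -1L))
  shift_mass <- if (length(formula_shift))
    sum(vapply(names(formula_shift), function(el)
      formula_shift[[el]] * .ISOTOPE_TABLE[[el]]$mass[1], numeric(1)))
  else 0
  if (abs(shift_mass + extra_mass - delta) > 1e-9)
    stop("inconsistent adduct definition for ", name,
         ": delta != mass(formula_shift) + extra_mass")
  structure(list(name = name, polarity = as.integer(polarity),
                 delta = delta, formula_shift = formula_shift,
                 extra_mass = extra_mass),
            class = "adduct_spec")
}

#' Default adduct registry
#'
#' The four adducts observed in the screening tables are always
#' registered: \[M+H\]+, \[M+H-H2O\]+, \[M+Na\]+ and \[M-H\]-.  The
#' registry is an ordinary list, so callers may append further
#' `adduct_spec`s.
#'
#' @return Named list of `adduct_spec` objects.
#' @export
default_adducts <- function() {
  hmass <- .ISOTOPE_TABLE$H$mass[1]
  omass <- .ISOTOPE_TABLE$O$mass[1]
  adducts <- list(
    adduct_spec("[M+H]+", +1L, .PROTON_MASS,
                formula_shift = c(H = 1L), extra_mass = -.ELECTRON_MASS),
    adduct_spec("[M+H-H2O]+", +1L, .PROTON_MASS - 2 * hmass - omass,
                formula_shift = c(H = -1L, O = -1L),
                extra_mass = -.ELECTRON_MASS),
    adduct_spec("[M+Na]+", +1L, .NA_MASS - .ELECTRON_MASS,
                formula_shift = integer(),
                extra_mass = .NA_MASS - .ELECTRON_MASS),
    adduct_spec("[M-H]-", -1L, -.PROTON_MASS,
                formula_shift = c(H = -1L), extra_mass = .ELECTRON_MASS)
  )
  stats::setNames(adducts, vapply(adducts, `[[`, character(1), "name"))
}

.find_adduct <- function(adduct, adducts = default_adducts()) {
  if (inherits(adduct, "adduct_spec")) return(adduct)
  if (!adduct %in% names(adducts))
    stop("unknown adduct '", adduct, "'; registered: ",
         paste(names(adducts), collapse = ", "))
  adducts[[adduct]]
}

#' Ion m/z of a neutral mass under an adduct
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct An `adduct_spec` or registered adduct name.
#' @param adducts Adduct registry (see [default_adducts()]).
#' @return Singly charged ion m/z in Da.
#' @export
ion_mz_from_neutral <- function(neutral_mass, adduct,
                                adducts = default_adducts()) {
  neutral_mass + .find_adduct(adduct, adducts)$delta
}

#' Neutral mass implied by an ion m/z under an adduct
#'
#' Inverts [ion_mz_from_neutral()]; round-trips to 1e-9 Da.
#'
#' @inheritParams ion_mz_from_neutral
#' @param mz Observed ion m/z (> 0).
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_ion <- function(mz, adduct, adducts = default_adducts()) {
  if (any(mz <= 0)) stop("ion m/z must be positive")
  mz - .find_adduct(adduct, adducts)$delta
}

#' Screening constraint set
#'
#' Bundles every tunable threshold of the screening workflow.  Defaults
#' are the workflow's standard values: 3 ppm mass tolerance, 20,000
#' minimum apex intensity, element ranges C 1-90 / H 1-190 / O 0-18 /
#' N 0-5 / S 0-1, 0.1 <= H/C <= 3.5, 0 <= DBE <= 40, S/N >= 3, minimum
#' peak area 1000, and the m/z 100-600 acquisition window.
#'
#' @param tol_ppm Mass tolerance in ppm for formula/ion matching.
#' @param min_intensity Minimum chromatographic apex intensity (counts).
#' @param c_range,h_range,o_range,n_range,s_range Integer length-2
#'   (min, max) element count ranges.
#' @param hc_min,hc_max Bounds on the H/C ratio.
#' @param dbe_min,dbe_max Bounds on the double-bond equivalent.
#' @param sn_min Minimum chromatographic signal-to-noise ratio.
#' @param min_peak_area Minimum integrated peak area (counts x min).
#' @param mz_min,mz_max Acquisition m/z window in Da.
#' @param rt_tol_min Retention-time tolerance (min) for blank matching.
#' @param shape_min Advisory Gaussian shape-score threshold in \[0,1\].
#' @return A `screening_constraints` list.
#' @export
screening_constraints <- function(tol_ppm = 3, min_intensity = 20000,
                                  c_range = c(1L, 90L), h_range = c(1L, 190L),
                                  o_range = c(0L, 18L), n_range = c(0L, 5L),
                                  s_range = c(0L, 1L),
                                  hc_min = 0.1, hc_max = 3.5,
                                  dbe_min = 0, dbe_max = 40,
                                  sn_min = 3, min_peak_area = 1000,
                                  mz_min = 100, mz_max = 600,
                                  rt_tol_min = 0.2, shape_min = 0.8) {
  cons <- list(tol_ppm = as.numeric(tol_ppm),
               min_intensity = as.numeric(min_intensity),
               c_range = as.integer(c_range), h_range = as.integer(h_range),
               o_range = as.integer(o_range), n_range = as.integer(n_range),
               s_range = as.integer(s_range),
               hc_min = as.numeric(hc_min), hc_max = as.numeric(hc_max),
               dbe_min = as.numeric(dbe_min), dbe_max = as.numeric(dbe_max),
               sn_min = as.numeric(sn_min),
               min_peak_area = as.numeric(min_peak_area),
               mz_min = as.numeric(mz_min), mz_max = as.numeric(mz_max),
               rt_tol_min = as.numeric(rt_tol_min),
               shape_min = as.numeric(shape_min))
  for (r in c("c_range", "h_range", "o_range", "n_range", "s_range"))
    if (length(cons[[r]]) != 2L || cons[[r]][1] > cons[[r]][2] ||
        cons[[r]][1] < 0L)
      stop("invalid element range ", r)
  stopifnot(is.finite(unlist(cons[c("tol_ppm", "min_intensity", "hc_min",
                                    "hc_max", "dbe_min", "dbe_max", "sn_min",
                                    "min_peak_area", "mz_min", "mz_max")])),
            cons$tol_ppm > 0, cons$hc_min <= cons$hc_max,
            cons$dbe_min <= cons$dbe_max, cons$mz_min < cons$mz_max)
  structure(cons, class = "screening_constraints")
}

#' Read screening constraints from a YAML config file
#'
#' Keys mirror the arguments of [screening_constraints()]; absent keys
#' keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `screening_constraints` list.
#' @export
constraints_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(screening_constraints))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown constraint key(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  do.call(screening_constraints, cfg)
}

# Enumerate CHNOS formulas with monoisotopic mass inside [lo, hi] that
# satisfy the H/C and DBE windows.  H is bracketed per (C, N, O, S) cell;
# every emitted formula is re-checked against the raw predicates so the
# bracketing can never admit a false positive.
.enumerate_mass_window <- function(lo, hi, cons) {
  mC <- .ISOTOPE_TABLE$C$mass[1]; mH <- .ISOTOPE_TABLE$H$mass[1]
  mN <- .ISOTOPE_TABLE$N$mass[1]; mO <- .ISOTOPE_TABLE$O$mass[1]
  mS <- .ISOTOPE_TABLE$S$mass[1]
  cmax <- min(cons$c_range[2], floor(hi / mC))
  if (cmax < cons$c_range[1])
    return(data.frame(formula = character(0), C = integer(0), H = integer(0),
                      N = integer(0), O = integer(0), S = integer(0),
                      mass = numeric(0), dbe = numeric(0), hc = numeric(0)))
  grid <- expand.grid(C = cons$c_range[1]:cmax,
                      N = cons$n_range[1]:cons$n_range[2],
                      O = cons$o_range[1]:cons$o_range[2],
                      S = cons$s_range[1]:cons$s_range[2])
  base <- grid$C * mC + grid$N * mN + grid$O * mO + grid$S * mS
  # H bracket from mass window, element range, H/C window and DBE window
  hlo <- pmax(cons$h_range[1],
              ceiling((lo - base) / mH - 1e-9),
              ceiling(cons$hc_min * grid$C - 1e-9),
              ceiling(2 * (grid$C + grid$N / 2 + 1 - cons$dbe_max) - 1e-9))
  hhi <- pmin(cons$h_range[2],
              floor((hi - base) / mH + 1e-9),
              floor(cons$hc_max * grid$C + 1e-9),
              floor(2 * (grid$C + grid$N / 2 + 1 - cons$dbe_min) + 1e-9))
  keep <- hlo <= hhi
  if (!any(keep))
    return(data.frame(formula = character(0), C = integer(0), H = integer(0),
                      N = integer(0), O = integer(0), S = integer(0),
                      mass = numeric(0), dbe = numeric(0), hc = numeric(0)))
  grid <- grid[keep, , drop = FALSE]
  base <- base[keep]; hlo <- hlo[keep]; hhi <- hhi[keep]
  reps <- hhi - hlo + 1
  idx <- rep.int(seq_len(nrow(grid)), reps)
  H <- unlist(lapply(seq_len(nrow(grid)), function(i) hlo[i]:hhi[i]),
              use.names = FALSE)
  out <- data.frame(C = grid$C[idx], H = as.integer(H), N = grid$N[idx],
                    O = grid$O[idx], S = grid$S[idx])
  out$mass <- base[idx] + out$H * mH
  out$dbe <- out$C - out$H / 2 + out$N / 2 + 1
  out$hc <- out$H / out$C
  # exact re-check of every predicate (soundness guarantee)
  ok <- out$mass >= lo & out$mass <= hi &
    out$hc >= cons$hc_min & out$hc <= cons$hc_max &
    out$dbe >= cons$dbe_min & out$dbe <= cons$dbe_max &
    out$H >= cons$h_range[1] & out$H <= cons$h_range[2]
  out <- out[ok, , drop = FALSE]
  out$formula <- .hill_string(out$C, out$H, out$N, out$O, out$S)
  out[c("formula", "C", "H", "N", "O", "S", "mass", "dbe", "hc")]
}

# Vectorized Hill-order formatter for enumeration output.
.hill_string <- function(C, H, N, O, S) {
  piece <- function(sym, n)
    ifelse(n == 0L, "", ifelse(n == 1L, sym, paste0(sym, n)))
  paste0(piece("C", C), piece("H", H), piece("N", N),
         piece("O", O), piece("S", S))
}

# Canonical candidate ordering: |ppm| ascending, then lower DBE, then
# Hill string.  (The ordering convention is this package's, not an
# instrument vendor's.)
.order_candidates <- function(df) {
  df[order(abs(df$ppm), df$dbe, df$formula), , drop = FALSE]
}

#' Enumerate candidate formulas for a neutral mass
#'
#' Returns every CHNOS formula inside the configured element ranges
#' whose monoisotopic mass lies within `tol_ppm` of `neutral_mass` and
#' whose H/C ratio and DBE fall inside the configured windows.  The
#' search is complete: it is tested to agree exactly with a naive grid
#' scan over the full element ranges.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param constraints A [screening_constraints()] list.
#' @return A data.frame with columns `formula`, `theoretical_mass`,
#'   `ppm` (signed, computed on the neutral mass), `dbe`, `hc`, sorted
#'   by absolute ppm, then DBE, then Hill string.
#' @examples
#' enumerate_formulas(146.036779)  # contains C9H6O2
#' @export
enumerate_formulas <- function(neutral_mass,
                               constraints = screening_constraints()) {
  if (neutral_mass <= 0) stop("neutral mass must be positive")
  t <- constraints$tol_ppm * 1e-6
  hits <- .enumerate_mass_window(neutral_mass / (1 + t),
                                 neutral_mass / (1 - t), constraints)
  out <- data.frame(formula = hits$formula, theoretical_mass = hits$mass,
                    ppm = ppm_error(neutral_mass, pmax(hits$mass, 1e-12)),
                    dbe = hits$dbe, hc = hits$hc)
  if (!nrow(out)) return(out)
  rownames(out) <- NULL
  out <- .order_candidates(out)
  rownames(out) <- NULL
  out
}

#' Assign candidate (formula, adduct) pairs to an observed ion m/z
#'
#' For each registered adduct of matching polarity, enumerates formulas
#' on the implied neutral mass and tags each candidate with its adduct.
#' The ppm error is computed on the ion m/z being matched.
#'
#' @param mz Observed ion m/z, inside the acquisition window.
#' @param polarity `"pos"`/`"neg"` (or `+1`/`-1`).
#' @param constraints A [screening_constraints()] list.
#' @param adducts Adduct registry.
#' @return A data.frame with columns `formula`, `adduct`,
#'   `theoretical_mz`, `ppm`, `dbe`, `hc`, sorted by absolute ppm, DBE,
#'   Hill string.
#' @export
assign_ion <- function(mz, polarity, constraints = screening_constraints(),
                       adducts = default_adducts()) {
  pol <- .polarity_sign(polarity)
  if (mz < constraints$mz_min || mz > constraints$mz_max)
    stop(sprintf("m/z %.4f outside the acquisition window [%g, %g]",
                 mz, constraints$mz_min, constraints$mz_max))
  t <- constraints$tol_ppm * 1e-6
  res <- list()
  for (ad in adducts) {
    if (ad$polarity != pol) next
    lo <- mz / (1 + t) - ad$delta
    hi <- mz / (1 - t) - ad$delta
    if (hi <= 0) next
    hits <- .enumerate_mass_window(max(lo, 1e-6), hi, constraints)
    if (!nrow(hits)) next
    theo_mz <- hits$mass + ad$delta
    res[[length(res) + 1L]] <- data.frame(
      formula = hits$formula, adduct = ad$name, theoretical_mz = theo_mz,
      ppm = ppm_error(mz, theo_mz), dbe = hits$dbe, hc = hits$hc)
  }
  if (!length(res))
    return(data.frame(formula = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm = numeric(0),
                      dbe = numeric(0), hc = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[abs(out$ppm) <= constraints$tol_ppm, , drop = FALSE]
  out <- .order_candidates(out)
  rownames(out) <- NULL
  out
}

.polarity_sign <- function(polarity) {
  if (is.numeric(polarity)) {
    stopifnot(polarity %in% c(1, -1))
    return(as.integer(polarity))
  }
  switch(match.arg(tolower(polarity), c("pos", "neg", "+", "-")),
         pos = , `+` = 1L, neg = , `-` = -1L)
}

.polarity_label <- function(polarity)
  if (.polarity_sign(polarity) > 0) "pos" else "neg"
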