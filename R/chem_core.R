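# Elemental formulas over CHNOS, monoisotopic masses, DBE/HC filters and
# ppm arithmetic.  Everything downstream (enumeration, isotope patterns,
# screening) builds on this file.

# Supported element set, in Hill order (C, H, then alphabetical).
.ELEMENTS <- c("C", "H", "N", "O", "S")

# Isotope masses (Da) and natural abundances, IUPAC 2013 / CODATA values.
# Masses strictly increasing per element; abundances sum to 1.
.ISOTOPE_TABLE <- list(
  C = list(mass = c(12.0, 13.00335483507),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503207, 2.01410177812),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.00307400443, 15.00010889888),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207117441, 32.97145890982, 33.96786700, 35.96708071),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Charge-carrier constants (Da).
.ELECTRON_MASS <- 0.000548579909
# proton = 1H minus its electron, so adduct arithmetic is exactly
# consistent with the isotope table (1.00727645216 Da)
.PROTON_MASS   <- 1.00782503207 - .ELECTRON_MASS
.NA_MASS       <- 22.98976928      # 23Na, effectively monoisotopic (100%)

#' Isotope table used by the package
#'
#' Per element, the isotope masses (Da, strictly increasing) and natural
#' abundance fractions (summing to 1) used for monoisotopic masses and
#' theoretical isotopologue patterns.
#'
#' @return A named list with one entry per supported element (C, H, N, O,
#'   S), each a list with numeric vectors `mass` and `abundance`.
#' @export
isotope_table <- function() .ISOTOPE_TABLE

#' Construct an elemental formula
#'
#' A formula is a named count vector over the supported element set
#' C, H, N, O, S.  The all-zero formula is the identity for formula
#' addition.
#'
#' @param counts Named integer vector or list, e.g. `c(C = 9, H = 6, O = 2)`.
#'   Elements outside C/H/N/O/S are rejected; counts must be non-negative
#'   integers.
#' @return An object of class `chem_formula`: an integer vector with one
#'   entry per supported element.
#' @examples
#' chem_formula(c(C = 9, H = 6, O = 2))
#' @export
chem_formula <- function(counts = integer()) {
  counts <- unlist(counts)
  if (length(counts) && is.null(names(counts)))
    stop("formula counts must be named by element symbol")
  bad <- setdiff(names(counts), .ELEMENTS)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(.ELEMENTS, collapse = ""), ")")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  out <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  out[names(counts)] <- as.integer(round(counts))
  structure(out, class = "chem_formula")
}

#' Parse a formula string
#'
#' Accepts Hill-order strings with or without explicit 1 counts
#' ("CH4" and "C1H4" are equivalent).
#'
#' @param x Formula string, e.g. `"C9H6O2"`.
#' @return A `chem_formula`.
#' @export
parse_formula <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("formula must be a single character string")
  x <- gsub("[[:space:]]", "", x)
  if (!nzchar(x)) return(chem_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  pieces <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse formula string: ", x)
  counts <- integer(0)
  for (p in pieces) {
    sym <- gsub("[0-9]", "", p)
    num <- gsub("[^0-9]", "", p)
    n <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  chem_formula(counts)
}

.as_formula <- function(f) {
  if (inherits(f, "chem_formula")) f else if (is.character(f))
    parse_formula(f) else chem_formula(f)
}

#' Format a formula in Hill order
#'
#' @param x A `chem_formula`.
#' @param ... Unused.
#' @return A string such as `"C9H6O2"`; the empty formula formats as `""`.
#' @export
format.chem_formula <- function(x, ...) {
  parts <- character(0)
  for (el in .ELEMENTS) {
    n <- x[[el]]
    if (n > 0L)
      parts <- c(parts, if (n == 1L) el else paste0(el, n))
  }
  paste(parts, collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Add two formulas element-wise
#'
#' @param f1,f2 `chem_formula` objects (or strings / named vectors).
#' @return Their element-wise sum as a `chem_formula`.
#' @export
formula_add <- function(f1, f2) {
  f1 <- .as_formula(f1); f2 <- .as_formula(f2)
  chem_formula(unclass(f1) + unclass(f2))
}

# Signed element-wise combination used by adduct arithmetic; may go
# negative transiently, so validated by the caller.
.formula_combine_raw <- function(f, delta) {
  out <- unclass(.as_formula(f))
  out[names(delta)] <- out[names(delta)] + delta
  out
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the lightest-isotope mass.
#'
#' @param f A `chem_formula`, formula string, or named count vector.
#' @return Mass in Da; 0 for the empty formula.
#' @examples
#' monoisotopic_mass("H2O")     # 18.010565
#' monoisotopic_mass("C9H6O2")  # coumarin, 146.036779
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  sum(vapply(.ELEMENTS, function(el)
    f[[el]] * .ISOTOPE_TABLE[[el]]$mass[1], numeric(1)))
}

#' Ring-plus-double-bond equivalent (DBE)
#'
#' DBE = C - H/2 + N/2 + 1; O and S contribute nothing.  May be
#' half-integral for odd-electron compositions.
#'
#' @param f A formula (any representation accepted by [chem_formula()]).
#' @return Dimensionless DBE.
#' @examples
#' dbe("CH4")     # 0
#' dbe("C9H6O2")  # 7
#' @export
dbe <- function(f) {
  f <- .as_formula(f)
  f[["C"]] - f[["H"]] / 2 + f[["N"]] / 2 + 1
}

#' Hydrogen-to-carbon ratio
#'
#' @param f A formula with at least one carbon.
#' @return H count divided by C count.
#' @export
hc_ratio <- function(f) {
  f <- .as_formula(f)
  if (f[["C"]] < 1L)
    stop("H/C ratio undefined for a formula without carbon")
  f[["H"]] / f[["C"]]
}

#' Signed mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values in Da; the theoretical
#'   value must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`, sign preserved.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0))
    stop("theoretical m/z must be positive")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}
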