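# MS/MS spectral normalization, square-root-intensity cosine matching,
# and library search with isomer-group handling, standing in for the
# proprietary cloud spectral-library confirmation step.

#' Construct an MS/MS spectrum
#'
#' @param precursor_mz Precursor ion m/z in Da.
#' @param frag_mz Fragment m/z values (each <= precursor + 1 Da).
#' @param frag_intensity Non-negative fragment intensities.
#' @param polarity `"pos"` or `"neg"`.
#' @return An `msms_spectrum` object (fragments sorted by m/z).
#' @export
msms_spectrum <- function(precursor_mz, frag_mz = numeric(),
                          frag_intensity = numeric(), polarity = "pos") {
  if (length(frag_mz) != length(frag_intensity))
    stop("fragment m/z and intensity must have equal length")
  if (any(frag_intensity < 0)) stop("fragment intensities must be >= 0")
  if (any(frag_mz > precursor_mz + 1))
    stop("fragment m/z above precursor + 1 Da")
  o <- order(frag_mz)
  structure(list(precursor_mz = precursor_mz,
                 frag_mz = as.numeric(frag_mz[o]),
                 frag_intensity = as.numeric(frag_intensity[o]),
                 polarity = .polarity_label(polarity)),
            class = "msms_spectrum")
}

#' Normalize an MS/MS spectrum to base fragment 1
#'
#' @param s An [msms_spectrum()] with at least one non-zero fragment.
#' @return The spectrum with intensities scaled so the base fragment is
#'   1 (idempotent).
#' @export
normalize_spectrum <- function(s) {
  if (!length(s$frag_mz)) stop("spectrum has no fragments")
  m <- max(s$frag_intensity)
  if (m <= 0) stop("all fragment intensities are zero")
  s$frag_intensity <- s$frag_intensity / m
  s
}

# Greedy fragment pairing: query fragments in decreasing intensity order
# each claim the unused reference fragment with the smallest |ppm|
# inside the tolerance.  Returns index pairs.
.pair_fragments <- function(query, ref, frag_tol_ppm) {
  used <- logical(length(ref$frag_mz))
  qi <- order(query$frag_intensity, decreasing = TRUE)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in qi) {
    dppm <- abs(ppm_error(query$frag_mz[i], ref$frag_mz))
    cand <- which(!used & dppm <= frag_tol_ppm)
    if (!length(cand)) next
    j <- cand[which.min(dppm[cand])]
    used[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

#' Spectral similarity score (% of a perfect match)
#'
#' Square-root-intensity match factor: after greedy fragment pairing
#' within `frag_tol_ppm`, the score is
#' `100 * (sum sqrt(q_i * r_i))^2 / (sum q * sum r)` - the squared
#' cosine of the square-root-intensity vectors over the fragment union.
#' Symmetric, scale-invariant, 100 for self-match, 0 for disjoint
#' fragment sets.  Set `sqrt_weight = FALSE` for the plain-intensity
#' variant.
#'
#' @param query,ref [msms_spectrum()] objects.
#' @param frag_tol_ppm Fragment pairing tolerance in ppm.
#' @param sqrt_weight Use square-root intensity weighting (default).
#' @return Score in \[0, 100\].
#' @export
cosine_score <- function(query, ref, frag_tol_ppm = 10, sqrt_weight = TRUE) {
  if (!length(query$frag_mz) || !length(ref$frag_mz)) return(0)
  q <- query$frag_intensity; r <- ref$frag_intensity
  if (!sqrt_weight) { q <- q^2; r <- r^2 }  # plain cosine = sqrt path on i^2
  pairs <- .pair_fragments(query, ref, frag_tol_ppm)
  if (!nrow(pairs)) return(0)
  num <- sum(sqrt(q[pairs[, 1]] * r[pairs[, 2]]))
  den <- sum(q) * sum(r)
  if (den <= 0) return(0)
  100 * num^2 / den
}

#' Create a spectral-library entry
#'
#' @param name Compound name (unique within a library).
#' @param formula Neutral formula (string or `chem_formula`).
#' @param spectrum Reference [msms_spectrum()].
#' @param isomer_group Optional group label shared by compounds
#'   indistinguishable by MS/MS (e.g. positional isomers); members of a
#'   group share a formula.
#' @return A `library_entry` object.
#' @export
library_entry <- function(name, formula, spectrum, isomer_group = NA_character_) {
  stopifnot(nzchar(name))
  structure(list(name = name, formula = .as_formula(formula),
                 spectrum = spectrum, isomer_group = isomer_group),
            class = "library_entry")
}

.validate_library <- function(library) {
  nms <- vapply(library, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate compound name(s) in library: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  grp <- vapply(library, `[[`, character(1), "isomer_group")
  for (g in unique(grp[!is.na(grp)])) {
    fs <- unique(vapply(library[which(grp == g)],
                        function(e) format(e$formula), character(1)))
    if (length(fs) > 1)
      stop("isomer group '", g, "' members do not share a formula")
  }
  invisible(library)
}

#' Search a spectral library for the best match to a query spectrum
#'
#' Restricts to entries whose reference precursor lies within
#' `precursor_tol_ppm` of the query precursor (and matching polarity),
#' scores each with [cosine_score()], and returns the best hit.  When
#' two or more entries within 1 score point of the top belong to a
#' single isomer group, the group label is reported instead of a single
#' name (positional isomers are not distinguishable by MS/MS).
#'
#' @param query An [msms_spectrum()].
#' @param library List of [library_entry()] objects (non-empty).
#' @param precursor_tol_ppm Precursor tolerance in ppm.
#' @param frag_tol_ppm Fragment pairing tolerance in ppm.
#' @return A list: `hit` (logical), `name` (compound or group label),
#'   `score` (%), `isomer_group` (label or NA).  `hit = FALSE` when no
#'   entry passes the precursor filter or every score is 0.
#' @export
library_search <- function(query, library, precursor_tol_ppm = 5,
                           frag_tol_ppm = 10) {
  if (!length(library)) stop("library is empty")
  .validate_library(library)
  no_hit <- list(hit = FALSE, name = NA_character_, score = 0,
                 isomer_group = NA_character_)
  keep <- vapply(library, function(e)
    e$spectrum$polarity == query$polarity &&
      abs(ppm_error(query$precursor_mz, e$spectrum$precursor_mz)) <=
        precursor_tol_ppm, logical(1))
  cand <- library[keep]
  if (!length(cand)) return(no_hit)
  scores <- vapply(cand, function(e)
    cosine_score(query, e$spectrum, frag_tol_ppm), numeric(1))
  if (max(scores) <= 0) return(no_hit)
  top <- which.max(scores)
  best <- cand[[top]]
  near <- which(scores >= scores[top] - 1)
  if (length(near) > 1 && !is.na(best$isomer_group)) {
    grps <- vapply(cand[near], `[[`, character(1), "isomer_group")
    if (all(!is.na(grps)) && all(grps == best$isomer_group))
      return(list(hit = TRUE, name = best$isomer_group,
                  score = scores[top], isomer_group = best$isomer_group))
  }
  list(hit = TRUE, name = best$name, score = scores[top],
       isomer_group = best$isomer_group)
}

#' Read a spectral library from JSON
#'
#' Expected shape: an array of objects with fields `name`, `formula`,
#' `precursor_mz`, `polarity`, `isomer_group` (optional), `frag_mz`,
#' `frag_intensity`.
#'
#' @param path JSON file path.
#' @return List of [library_entry()] objects.
#' @export
read_msms_library_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lib <- lapply(obj, function(e) {
    sp <- msms_spectrum(e$precursor_mz, unlist(e$frag_mz),
                        unlist(e$frag_intensity), e$polarity)
    grp <- if (is.null(e$isomer_group)) NA_character_ else e$isomer_group
    library_entry(e$name, e$formula, sp, grp)
  })
  .validate_library(lib)
}

#' Write a spectral library to JSON
#'
#' @param library List of [library_entry()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msms_library_json <- function(library, path) {
  obj <- lapply(library, function(e)
    list(name = e$name, formula = format(e$formula),
         precursor_mz = e$spectrum$precursor_mz,
         polarity = e$spectrum$polarity,
         isomer_group = if (is.na(e$isomer_group)) NULL else e$isomer_group,
         frag_mz = e$spectrum$frag_mz,
         frag_intensity = e$spectrum$frag_intensity))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a spectral library from MSP-style text
#'
#' Supports the minimal MSP dialect: per entry `Name:`, `Formula:`,
#' `PrecursorMZ:`, optional `Polarity:` (`Positive`/`Negative`) and
#' `IsomerGroup:`, then `Num Peaks: n` followed by `n` lines of
#' whitespace-separated `m/z intensity`.  Entries are separated by
#' blank lines.
#'
#' @param path MSP file path.
#' @return List of [library_entry()] objects.
#' @export
read_msms_library_msp <- function(path) {
  lines <- readLines(path)
  lib <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    meta <- list(polarity = "pos", isomer_group = NA_character_)
    while (i <= n && grepl(":", lines[i], fixed = TRUE)) {
      key <- trimws(sub(":.*", "", lines[i]))
      val <- trimws(sub("^[^:]*:", "", lines[i]))
      i <- i + 1L
      switch(tolower(gsub("[[:space:]]", "", key)),
             name = { meta$name <- val },
             formula = { meta$formula <- val },
             precursormz = { meta$precursor_mz <- as.numeric(val) },
             polarity = { meta$polarity <-
               if (tolower(substr(val, 1, 1)) == "n") "neg" else "pos" },
             isomergroup = { meta$isomer_group <- val },
             numpeaks = { meta$npeaks <- as.integer(val) },
             NULL)
      if (!is.null(meta$npeaks)) break
    }
    if (is.null(meta$name) || is.null(meta$precursor_mz) ||
        is.null(meta$npeaks))
      stop("malformed MSP entry near line ", i)
    pk <- utils::read.table(text = lines[i:(i + meta$npeaks - 1L)],
                            col.names = c("mz", "intensity"))
    i <- i + meta$npeaks
    sp <- msms_spectrum(meta$precursor_mz, pk$mz, pk$intensity,
                        meta$polarity)
    lib[[length(lib) + 1L]] <-
      library_entry(meta$name, meta$formula, sp, meta$isomer_group)
  }
  .validate_library(lib)
}
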