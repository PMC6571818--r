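# The formula-validation checklist (blank / noise / shape / isotope /
# database counts / MS-MS), the confirmation predicate, polarity
# merging, report rendering, and replay of the packaged checklist
# fixtures.

#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata/` directory; with
#'   no argument, lists the available fixtures.
#' @return Full path (or a vector of file names).
#' @export
leafscreen_extdata <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "leafscreen")))
  path <- system.file("extdata", file, package = "leafscreen")
  if (!nzchar(path)) stop("no packaged fixture called ", file)
  path
}

#' Default isomer groups
#'
#' Compounds indistinguishable by MS/MS, reported under a shared group
#' label when the library search cannot separate them (positional
#' isomers of methoxybenzaldehyde being the packaged example).
#'
#' @return Named list: group label -> member compound names.
#' @export
default_isomer_groups <- function() {
  list("3 or 4 methoxybenzaldehyde" =
         c("3-Methoxybenzaldehyde", "4-Methoxybenzaldehyde"))
}

#' Parse an MS/MS checklist cell
#'
#' Checklist cells use the vocabulary `"no MS/MS"` (no spectrum was
#' acquired for the precursor), `"no match"` (a spectrum was acquired
#' but nothing in the library matched), a bare score such as `"80%"` or
#' `"96.8"` (a library hit on the compound's own name), or
#' `"Name, 61%"` (a hit on a different compound or an isomer-group
#' label).
#'
#' @param cell The cell string.
#' @param own_name The row's compound name (attributed to bare scores).
#' @return A list: `type` (`"no_msms"`, `"no_match"` or `"hit"`),
#'   `name` (matched name or NA), `score` (numeric % or NA).
#' @export
parse_msms_cell <- function(cell, own_name) {
  cell <- trimws(cell)
  if (tolower(cell) %in% c("no ms/ms", "no msms"))
    return(list(type = "no_msms", name = NA_character_, score = NA_real_))
  if (tolower(cell) == "no match")
    return(list(type = "no_match", name = NA_character_, score = NA_real_))
  bare <- gsub("%", "", cell, fixed = TRUE)
  if (grepl("^[0-9.]+$", bare))
    return(list(type = "hit", name = own_name, score = as.numeric(bare)))
  m <- regmatches(cell, regexec("^(.*),\\s*([0-9.]+)\\s*%*$", cell))[[1]]
  if (length(m) == 3L)
    return(list(type = "hit", name = trimws(m[2]), score = as.numeric(m[3])))
  stop("cannot parse MS/MS cell: '", cell, "'")
}

#' Format a library-search result as a checklist cell
#'
#' @param hit A [library_search()] result.
#' @param acquired Was an MS/MS spectrum acquired for the precursor?
#' @return A cell string in the [parse_msms_cell()] vocabulary.
#' @export
format_msms_cell <- function(hit, acquired = TRUE) {
  if (!acquired) return("no MS/MS")
  if (!hit$hit) return("no match")
  sprintf("%s, %.1f%%", hit$name, hit$score)
}

# Is the matched name consistent with the row's compound name?  Direct
# normalized equality, or membership of a shared isomer group (either
# via the group label or via two member names).
.name_consistent <- function(match_name, row_name, isomer_groups,
                             collapse_stereo = FALSE) {
  mk <- normalize_name(match_name, collapse_stereo)
  rk <- normalize_name(row_name, collapse_stereo)
  if (mk == rk) return(TRUE)
  for (label in names(isomer_groups)) {
    members <- vapply(isomer_groups[[label]], normalize_name, character(1),
                      collapse_stereo = collapse_stereo)
    lk <- normalize_name(label, collapse_stereo)
    if (rk %in% members && (mk == lk || mk %in% members)) return(TRUE)
  }
  FALSE
}

.empty_rows <- function() {
  data.frame(name = character(0), rt = numeric(0),
             not_in_blank = logical(0), above_noise = logical(0),
             good_peak_shape = logical(0), isotopic_match = character(0),
             chemspider_matches = integer(0),
             extractables_matches = integer(0), msms = character(0),
             stringsAsFactors = FALSE)
}

#' Read a packaged-format validation checklist CSV
#'
#' Columns: `name`, `rt`, `not_in_blank`, `above_noise`,
#' `good_peak_shape` (logicals), `isotopic_match` (adduct label such as
#' `"[M+H]"`, or `"none"`), `chemspider_matches`,
#' `extractables_matches` (integers, 0 = no match), `msms` (cell in the
#' [parse_msms_cell()] vocabulary).
#'
#' @param path CSV path.
#' @return A validation-row data.frame.
#' @export
read_validation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- names(.empty_rows())
  if (!identical(names(df), need))
    stop("validation table must have exactly the columns: ",
         paste(need, collapse = ", "))
  for (cell in df$msms) parse_msms_cell(cell, "x")  # validate vocabulary
  df
}

#' Write a validation checklist CSV
#'
#' Inverse of [read_validation_table()]; round-trips exactly.
#'
#' @param rows Validation-row data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_table <- function(rows, path) {
  utils::write.csv(rows[names(.empty_rows())], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Run the validation checklist for one candidate compound
#'
#' Executes the checklist steps in order against the sample and blank
#' runs: (1) presence in the blank, (2) apex intensity, S/N and peak
#' area against the noise gates, (3) Gaussian peak shape (advisory),
#' (4) isotopic pattern per adduct, and (7) MS/MS library search on the
#' acquired data-dependent spectra.  Database structure counts (steps
#' 5-6) require external services and are reported as NA here; they
#' carry no weight in confirmation.  Evidence absence is recorded
#' (`"no MS/MS"`), never raised.
#'
#' @param candidate List with `name` and `formula` (plus optional
#'   `rt_hint` in minutes to disambiguate isomeric features).
#' @param sample,blank Sample and blank [lcms_run()]s (same polarity;
#'   the blank is mandatory - step 1 cannot run without it).
#' @param library MS/MS spectral library (list of [library_entry()]).
#' @param constraints A [screening_constraints()] list.
#' @param adducts Adduct registry.
#' @return A one-row validation data.frame (see
#'   [read_validation_table()] for the columns), or NULL when no
#'   chromatographic peak at all can be anchored for any adduct.
#' @export
validate_candidate <- function(candidate, sample, blank, library = list(),
                               constraints = screening_constraints(),
                               adducts = default_adducts()) {
  if (missing(blank) || is.null(blank))
    stop("a blank run is required: checklist step 1 is mandatory")
  if (blank$polarity != sample$polarity)
    stop("sample and blank runs must share a polarity")
  pol <- .polarity_sign(sample$polarity)
  f <- .as_formula(candidate$formula)
  neutral <- monoisotopic_mass(f)
  relaxed <- constraints
  relaxed$sn_min <- 0; relaxed$min_peak_area <- 0
  relaxed$min_intensity <- constraints$min_intensity * 0.05
  best <- NULL
  for (ad in adducts) {
    if (ad$polarity != pol) next
    mz <- neutral + ad$delta
    if (mz < constraints$mz_min || mz > constraints$mz_max) next
    trace <- build_eic(sample, mz, constraints$tol_ppm)
    peaks <- detect_peaks(trace, relaxed)
    if (!nrow(peaks)) next
    k <- if (!is.null(candidate$rt_hint))
      which.min(abs(peaks$rt_apex - candidate$rt_hint))
    else which.max(peaks$height)
    cand <- list(peak = peaks[k, ], trace = trace, adduct = ad, mz = mz)
    if (is.null(best) || cand$peak$height > best$peak$height)
      best <- cand
  }
  if (is.null(best)) return(NULL)
  peak <- best$peak
  above_noise <- peak$height >= constraints$min_intensity &&
    peak$sn >= constraints$sn_min && peak$area >= constraints$min_peak_area
  not_in_blank <- !present_in_blank(peak, blank, best$mz,
                                    constraints$rt_tol_min, constraints)
  good_shape <- peak$shape >= constraints$shape_min
  # step 4: isotopic pattern, trying each in-range adduct of the polarity
  iso_label <- "none"
  apex_idx <- which.min(abs(vapply(sample$spectra, `[[`, numeric(1), "rt") -
                              peak$rt_apex))
  apex_spec <- sample$spectra[[apex_idx]]
  for (ad in adducts) {
    if (ad$polarity != pol) next
    mz <- neutral + ad$delta
    if (mz < constraints$mz_min || mz > constraints$mz_max) next
    pat <- tryCatch(theoretical_pattern(f, ad, adducts = adducts),
                    error = function(e) NULL)
    if (is.null(pat)) next
    res <- match_pattern(apex_spec, pat, mz_tol_ppm = constraints$tol_ppm + 2)
    if (res$matched) { iso_label <- sub("[+-]$", "", ad$name); break }
  }
  # step 7: MS/MS on the acquired data-dependent spectra
  acq <- Filter(function(ms)
    abs(ppm_error(ms$precursor_mz, best$mz)) <= 10 &&
      attr(ms, "rt") >= peak$rt_left - 0.1 &&
      attr(ms, "rt") <= peak$rt_right + 0.1, sample$msms)
  if (!length(acq)) {
    msms_cell <- "no MS/MS"
  } else if (!length(library)) {
    msms_cell <- "no match"
  } else {
    rts <- vapply(acq, function(ms) abs(attr(ms, "rt") - peak$rt_apex),
                  numeric(1))
    hit <- library_search(acq[[which.min(rts)]], library,
                          precursor_tol_ppm = 10, frag_tol_ppm = 10)
    msms_cell <- format_msms_cell(hit)
  }
  data.frame(name = candidate$name, rt = round(peak$rt_apex, 2),
             not_in_blank = not_in_blank, above_noise = above_noise,
             good_peak_shape = good_shape, isotopic_match = iso_label,
             chemspider_matches = NA_integer_,
             extractables_matches = NA_integer_, msms = msms_cell,
             stringsAsFactors = FALSE)
}

#' Confirm toxic compounds from validation rows
#'
#' A row is confirmed when it is not in the blank, above noise, its
#' isotopic pattern matched, and its MS/MS cell is a library hit whose
#' matched name (or isomer-group label) is consistent with the row's
#' own compound at a score at or above `score_threshold_pct`.  Peak
#' shape is advisory and NOT required: a compound can be confirmed with
#' a flagged shape.  Hits on a different compound name are rejected.
#'
#' @param rows Validation-row data.frame.
#' @param score_threshold_pct Minimum MS/MS score (%), default 75.
#' @param isomer_groups Named list of isomer groups
#'   (see [default_isomer_groups()]).
#' @param collapse_stereo Passed to name normalization.
#' @return The confirmed subset of `rows`.
#' @export
confirm_toxic <- function(rows, score_threshold_pct = 75,
                          isomer_groups = default_isomer_groups(),
                          collapse_stereo = FALSE) {
  if (!nrow(rows)) return(rows)
  keep <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (!isTRUE(r$not_in_blank) || !isTRUE(r$above_noise)) return(FALSE)
    if (is.na(r$isotopic_match) || r$isotopic_match == "none") return(FALSE)
    ms <- parse_msms_cell(r$msms, r$name)
    if (ms$type != "hit" || ms$score < score_threshold_pct) return(FALSE)
    .name_consistent(ms$name, r$name, isomer_groups, collapse_stereo)
  }, logical(1))
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge confirmed compounds across polarities
#'
#' Union by normalized name; per-mode provenance recorded, and when a
#' compound is confirmed in both modes the reported retention time and
#' score come from the mode with the higher MS/MS score.
#'
#' @param pos_confirmed,neg_confirmed Confirmed validation-row
#'   data.frames (from [confirm_toxic()]) or plain character vectors of
#'   names.
#' @param collapse_stereo Passed to name normalization.
#' @return A data.frame with columns `name`, `modes` (`"pos"`, `"neg"`
#'   or `"both"`), `rt`, `msms_score`; no normalized-name duplicates.
#' @export
merge_polarities <- function(pos_confirmed, neg_confirmed,
                             collapse_stereo = FALSE) {
  std <- function(x, mode) {
    if (is.character(x))
      x <- data.frame(name = x, rt = NA_real_, msms = NA_character_,
                      stringsAsFactors = FALSE)
    if (!nrow(x))
      return(data.frame(name = character(0), rt = numeric(0),
                        score = numeric(0), mode = character(0)))
    score <- vapply(seq_len(nrow(x)), function(i) {
      if (is.na(x$msms[i])) return(NA_real_)
      parse_msms_cell(x$msms[i], x$name[i])$score
    }, numeric(1))
    data.frame(name = x$name, rt = x$rt, score = score,
               mode = mode, stringsAsFactors = FALSE)
  }
  all <- rbind(std(pos_confirmed, "pos"), std(neg_confirmed, "neg"))
  if (!nrow(all))
    return(data.frame(name = character(0), modes = character(0),
                      rt = numeric(0), msms_score = numeric(0)))
  key <- vapply(all$name, normalize_name, character(1),
                collapse_stereo = collapse_stereo)
  out <- lapply(unique(key), function(k) {
    grp <- all[key == k, , drop = FALSE]
    best <- grp[order(-ifelse(is.na(grp$score), -1, grp$score))[1], ]
    data.frame(name = best$name,
               modes = if (length(unique(grp$mode)) > 1) "both"
                       else grp$mode[1],
               rt = best$rt, msms_score = best$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Screen a sample run against a toxin table (one polarity)
#'
#' The non-targeted path: features are discovered by clustering
#' centroids above the intensity floor in m/z and detecting peaks in
#' each cluster's EIC; candidate formulas are assigned to each feature
#' under the constraint set; identities are taken from toxin-table
#' records sharing an assigned formula; and each identified candidate
#' is run through the full validation checklist.
#'
#' @param sample,blank Sample and blank [lcms_run()]s of one polarity.
#' @param toxdb A [read_toxin_db()] database.
#' @param library MS/MS spectral library.
#' @param constraints A [screening_constraints()] list.
#' @param adducts Adduct registry.
#' @return A validation-row data.frame, one row per identified
#'   candidate compound (rows that pass the noise gates).
#' @export
screen_run <- function(sample, blank, toxdb, library = list(),
                       constraints = screening_constraints(),
                       adducts = default_adducts()) {
  feats <- find_features(sample, constraints)
  seen <- character(0)
  rows <- list()
  for (i in seq_len(nrow(feats))) {
    cands <- assign_ion(feats$mz[i], sample$polarity, constraints, adducts)
    for (fml in unique(cands$formula)) {
      ri <- which(toxdb$formula_keys == fml)
      for (j in ri) {
        nm <- toxdb$records[[j]]$canonical_name
        if (nm %in% seen) next
        seen <- c(seen, nm)
        row <- validate_candidate(
          list(name = nm, formula = fml, rt_hint = feats$rt_apex[i]),
          sample, blank, library, constraints, adducts)
        if (!is.null(row) && isTRUE(row$above_noise))
          rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (!length(rows)) return(.empty_rows())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discover features in a run
#'
#' Centroids at or above the minimum intensity are pooled across scans
#' and clustered in m/z (gaps wider than twice the mass tolerance split
#' clusters); each cluster's intensity-weighted mean m/z is extracted
#' as an EIC and peaks detected under the full gates.
#'
#' @param run An [lcms_run()].
#' @param constraints A [screening_constraints()] list.
#' @return A data.frame of features: `mz`, `rt_apex`, `height`, `area`,
#'   `sn`, `shape`.
#' @export
find_features <- function(run, constraints = screening_constraints()) {
  mzs <- unlist(lapply(run$spectra, function(sp)
    sp$mz[sp$intensity >= constraints$min_intensity]))
  ints <- unlist(lapply(run$spectra, function(sp)
    sp$intensity[sp$intensity >= constraints$min_intensity]))
  empty <- data.frame(mz = numeric(0), rt_apex = numeric(0),
                      height = numeric(0), area = numeric(0),
                      sn = numeric(0), shape = numeric(0))
  if (!length(mzs)) return(empty)
  o <- order(mzs); mzs <- mzs[o]; ints <- ints[o]
  gap <- diff(mzs) / utils::head(mzs, -1) * 1e6
  cluster <- cumsum(c(0, gap > 2 * constraints$tol_ppm))
  out <- list()
  for (cl in unique(cluster)) {
    sel <- cluster == cl
    mz_ref <- sum(mzs[sel] * ints[sel]) / sum(ints[sel])
    trace <- build_eic(run, mz_ref, constraints$tol_ppm)
    peaks <- detect_peaks(trace, constraints)
    if (nrow(peaks))
      out[[length(out) + 1L]] <-
        data.frame(mz = mz_ref, rt_apex = peaks$rt_apex,
                   height = peaks$height, area = peaks$area, sn = peaks$sn,
                   shape = peaks$shape)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$mz, res$rt_apex), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble a screening report across both polarities
#'
#' @param pos_rows,neg_rows Validation-row data.frames for the two
#'   polarities.
#' @param score_threshold_pct Confirmation threshold (see
#'   [confirm_toxic()]).
#' @param isomer_groups Isomer groups for name consistency.
#' @param collapse_stereo Passed to name normalization.
#' @return A `screening_report`: list with `pos_rows`, `neg_rows`,
#'   `confirmed_pos`, `confirmed_neg`, `toxic` (the merged list).
#' @export
screening_report <- function(pos_rows, neg_rows, score_threshold_pct = 75,
                             isomer_groups = default_isomer_groups(),
                             collapse_stereo = FALSE) {
  cp <- confirm_toxic(pos_rows, score_threshold_pct, isomer_groups,
                      collapse_stereo)
  cn <- confirm_toxic(neg_rows, score_threshold_pct, isomer_groups,
                      collapse_stereo)
  structure(list(pos_rows = pos_rows, neg_rows = neg_rows,
                 confirmed_pos = cp, confirmed_neg = cn,
                 toxic = merge_polarities(cp, cn, collapse_stereo)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(paste0("<screening_report> %d positive-mode rows (%d ",
                     "confirmed), %d negative-mode rows (%d confirmed), ",
                     "%d toxic compounds total\n"),
              nrow(x$pos_rows), nrow(x$confirmed_pos),
              nrow(x$neg_rows), nrow(x$confirmed_neg), nrow(x$toxic)))
  if (nrow(x$toxic)) {
    cat("confirmed toxic compounds:\n")
    for (i in seq_len(nrow(x$toxic)))
      cat(sprintf("  %-28s (%s)\n", x$toxic$name[i], x$toxic$modes[i]))
  }
  invisible(x)
}

#' Write a screening report to CSV files
#'
#' Writes `table_pos.csv` and `table_neg.csv` (the per-mode validation
#' checklists, exactly the packaged-fixture column set) and
#' `toxic_compounds.csv` (the merged confirmed list) under `dir`.
#'
#' @param report A [screening_report()].
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(pos = file.path(dir, "table_pos.csv"),
             neg = file.path(dir, "table_neg.csv"),
             toxic = file.path(dir, "toxic_compounds.csv"))
  write_validation_table(report$pos_rows, files["pos"])
  write_validation_table(report$neg_rows, files["neg"])
  utils::write.csv(report$toxic, files["toxic"], row.names = FALSE)
  invisible(files)
}

#' Replay the packaged checklist fixtures
#'
#' Loads the packaged per-mode candidate lists, toxin table and
#' validation checklists, cross-references the candidates, applies the
#' confirmation predicate and merges polarities - the desk-scale replay
#' of the screening outcome.
#'
#' @param score_threshold_pct Confirmation threshold.
#' @return A list with the intermediate objects (`crossref_pos`,
#'   `crossref_neg`, `overlap`, `confirmed_pos`, `confirmed_neg`,
#'   `toxic`) and their counts (`n_pos`, `n_neg`, `n_overlap`,
#'   `n_confirmed_pos`, `n_confirmed_neg`, `n_toxic`).
#' @export
replay_fixtures <- function(score_threshold_pct = 75) {
  toxdb <- read_toxin_db(leafscreen_extdata("toxins.csv"))
  cand_pos <- utils::read.csv(leafscreen_extdata("candidates_pos.csv"),
                              stringsAsFactors = FALSE)
  cand_neg <- utils::read.csv(leafscreen_extdata("candidates_neg.csv"),
                              stringsAsFactors = FALSE)
  x_pos <- crossref(cand_pos, toxdb)
  x_neg <- crossref(cand_neg, toxdb)
  overlap <- polarity_overlap(x_pos$name, x_neg$name)
  t1 <- read_validation_table(leafscreen_extdata("table1_validation.csv"))
  t2 <- read_validation_table(leafscreen_extdata("table2_validation.csv"))
  c1 <- confirm_toxic(t1, score_threshold_pct)
  c2 <- confirm_toxic(t2, score_threshold_pct)
  toxic <- merge_polarities(c1, c2)
  list(crossref_pos = x_pos, crossref_neg = x_neg, overlap = overlap,
       table_pos = t1, table_neg = t2,
       confirmed_pos = c1, confirmed_neg = c2, toxic = toxic,
       n_pos = nrow(x_pos), n_neg = nrow(x_neg),
       n_overlap = length(overlap),
       n_confirmed_pos = nrow(c1), n_confirmed_neg = nrow(c2),
       n_toxic = nrow(toxic))
}
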