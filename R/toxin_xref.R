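# Cross-referencing identified candidate compounds against a
# food-toxin hazard table (OpenFoodTox-style CSV), with name
# normalization, synonym handling and formula fallback.

#' Normalize a compound name to a matching key
#'
#' Case-folds, collapses whitespace and strips punctuation other than
#' hyphens, so `"L-Glutamic acid"` and `"l-glutamic  ACID"` share a
#' key.  Stereodescriptor prefixes (L-, D-, DL-) are preserved as
#' distinct by default; `collapse_stereo = TRUE` strips a leading
#' stereo prefix, for the looser matching mode.
#'
#' @param name Non-empty compound name.
#' @param collapse_stereo Strip leading L-/D-/DL- prefixes.
#' @return Canonical key string.
#' @export
normalize_name <- function(name, collapse_stereo = FALSE) {
  if (any(!nzchar(trimws(name))))
    stop("compound name must be non-empty")
  key <- tolower(trimws(name))
  key <- gsub("[^a-z0-9[:space:]-]", "", key)
  key <- gsub("[[:space:]]+", " ", key)
  if (collapse_stereo)
    key <- sub("^(dl|d|l)-", "", key)
  key
}

#' Load a toxin hazard table from CSV
#'
#' Strict header: `canonical_name`, `synonyms` (pipe-delimited, may be
#' empty), `formula` (Hill string or empty), `hazard_note`.  Canonical
#' names must be unique after normalization and synonyms must not
#' collide across records.
#'
#' @param path CSV file path.
#' @param collapse_stereo Passed to [normalize_name()] for key building.
#' @return A `toxin_db`: list of records, each with `canonical_name`,
#'   `synonyms`, `formula` (a `chem_formula` or NULL), `hazard_note`,
#'   plus lookup keys.
#' @export
read_toxin_db <- function(path, collapse_stereo = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("canonical_name", "synonyms", "formula", "hazard_note")
  if (!identical(names(df), need))
    stop("toxin DB must have exactly the columns: ",
         paste(need, collapse = ", "))
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!nzchar(trimws(row$canonical_name)))
      stop("toxin DB row ", i, ": empty canonical_name")
    f <- tryCatch(
      if (nzchar(trimws(row$formula))) parse_formula(row$formula) else NULL,
      error = function(e)
        stop("toxin DB row ", i, ": bad formula '", row$formula, "'"))
    syn <- trimws(strsplit(row$synonyms, "|", fixed = TRUE)[[1]])
    syn <- syn[nzchar(syn)]
    records[[i]] <- list(canonical_name = row$canonical_name,
                         synonyms = syn, formula = f,
                         hazard_note = row$hazard_note)
  }
  db <- structure(list(records = records,
                       collapse_stereo = collapse_stereo),
                  class = "toxin_db")
  .index_toxin_db(db)
}

# Build name/synonym/formula lookup tables, checking collisions.
.index_toxin_db <- function(db) {
  cs <- db$collapse_stereo
  canon <- vapply(db$records, function(r)
    normalize_name(r$canonical_name, cs), character(1))
  if (anyDuplicated(canon))
    stop("duplicate canonical name(s) after normalization: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  syn_key <- character(0); syn_rec <- integer(0)
  for (i in seq_along(db$records)) {
    s <- db$records[[i]]$synonyms
    if (length(s)) {
      k <- vapply(s, normalize_name, character(1), collapse_stereo = cs)
      syn_key <- c(syn_key, k); syn_rec <- c(syn_rec, rep(i, length(k)))
    }
  }
  dup <- syn_key[duplicated(syn_key)]
  if (length(dup))
    stop("synonym(s) collide across records: ",
         paste(unique(dup), collapse = ", "))
  db$canon_keys <- canon
  db$syn_keys <- syn_key
  db$syn_record <- syn_rec
  db$formula_keys <- vapply(db$records, function(r)
    if (is.null(r$formula)) NA_character_ else format(r$formula),
    character(1))
  db
}

#' @export
print.toxin_db <- function(x, ...) {
  cat(sprintf("<toxin_db> %d records (%d with formulas, %d synonyms)\n",
              length(x$records), sum(!is.na(x$formula_keys)),
              length(x$syn_keys)))
  invisible(x)
}

# Look up one candidate: returns list(record index, rule) or NULL.
.toxdb_lookup <- function(db, name, formula = NULL) {
  if (!is.null(name) && !is.na(name) && nzchar(trimws(name))) {
    key <- normalize_name(name, db$collapse_stereo)
    i <- match(key, db$canon_keys)
    if (!is.na(i)) return(list(index = i, rule = "name"))
    j <- match(key, db$syn_keys)
    if (!is.na(j)) return(list(index = db$syn_record[j], rule = "synonym"))
    return(NULL)  # named candidates match by name only
  }
  if (!is.null(formula)) {
    i <- match(format(.as_formula(formula)), db$formula_keys)
    if (!is.na(i)) return(list(index = i, rule = "formula"))
  }
  NULL
}

#' Cross-reference candidate compounds against the toxin table
#'
#' A candidate matches when its normalized name (or any synonym of a
#' record) equals a record's canonical name, or - for name-less
#' candidates - when its formula equals a record's formula.  Candidate
#' order is preserved; each match carries the hazard annotation and an
#' explicit rule tag.
#'
#' @param candidates A data.frame with at least a `name` column;
#'   optional `formula` (Hill strings; used only when `name` is empty
#'   or NA) and any further evidence columns, which are passed through.
#' @param toxdb A [read_toxin_db()] database.
#' @return The matching subset of `candidates` with added columns
#'   `toxin_name` (the record's canonical name), `hazard_note` and
#'   `match_rule` (`"name"`, `"synonym"` or `"formula"`).
#' @export
crossref <- function(candidates, toxdb) {
  stopifnot(inherits(toxdb, "toxin_db"), "name" %in% names(candidates))
  hits <- integer(0); rules <- character(0); recs <- integer(0)
  for (i in seq_len(nrow(candidates))) {
    nm <- candidates$name[i]
    f <- if ("formula" %in% names(candidates) &&
             !is.na(candidates$formula[i]) &&
             nzchar(candidates$formula[i])) candidates$formula[i] else NULL
    m <- .toxdb_lookup(toxdb, nm, f)
    if (!is.null(m)) {
      hits <- c(hits, i); rules <- c(rules, m$rule); recs <- c(recs, m$index)
    }
  }
  out <- candidates[hits, , drop = FALSE]
  out$toxin_name <- vapply(recs, function(i)
    toxdb$records[[i]]$canonical_name, character(1))
  out$hazard_note <- vapply(recs, function(i)
    toxdb$records[[i]]$hazard_note, character(1))
  out$match_rule <- rules
  rownames(out) <- NULL
  out
}

#' Compounds found in both polarities
#'
#' @param pos_names,neg_names Character vectors of compound names from
#'   the positive- and negative-mode match lists.
#' @param collapse_stereo Passed to [normalize_name()].
#' @return The (positive-mode spelling of the) names whose normalized
#'   keys appear in both lists.
#' @export
polarity_overlap <- function(pos_names, neg_names, collapse_stereo = FALSE) {
  kp <- vapply(pos_names, normalize_name, character(1),
               collapse_stereo = collapse_stereo)
  kn <- vapply(neg_names, normalize_name, character(1),
               collapse_stereo = collapse_stereo)
  unname(pos_names[!duplicated(kp) & kp %in% kn])
}
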