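# Centroid spectra, LC-MS runs, extracted-ion chromatograms, peak
# detection with S/N and area gates, Gaussian shape scoring, and the
# blank-run comparison used by validation step 1.

#' Construct a centroid mass spectrum
#'
#' @param rt Retention time in minutes.
#' @param mz Numeric vector of centroid m/z values, strictly increasing.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param polarity `"pos"` or `"neg"`.
#' @return A `centroid_spectrum` object.
#' @export
centroid_spectrum <- function(rt, mz = numeric(), intensity = numeric(),
                              polarity = "pos") {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) > 1L && any(diff(mz) <= 0))
    stop("centroid m/z values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(rt = rt, mz = as.numeric(mz),
                 intensity = as.numeric(intensity),
                 polarity = .polarity_label(polarity)),
            class = "centroid_spectrum")
}

#' Construct an LC-MS run
#'
#' @param spectra List of [centroid_spectrum()] objects with
#'   non-decreasing retention times and a single shared polarity.
#' @param label `"sample"` or `"blank"`.
#' @param polarity `"pos"` or `"neg"`.
#' @param msms Optional list of [msms_spectrum()] objects acquired
#'   data-dependently during the run (each carries an `rt` attribute).
#' @return An `lcms_run` object.
#' @export
lcms_run <- function(spectra, label = c("sample", "blank"),
                     polarity = "pos", msms = list()) {
  label <- match.arg(label)
  polarity <- .polarity_label(polarity)
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (length(rts) > 1L && any(diff(rts) < 0))
    stop("spectra must be ordered by non-decreasing retention time")
  pols <- vapply(spectra, `[[`, character(1), "polarity")
  if (length(pols) && any(pols != polarity))
    stop("all spectra in a run must share the run polarity")
  structure(list(spectra = spectra, label = label, polarity = polarity,
                 msms = msms),
            class = "lcms_run")
}

#' @export
print.lcms_run <- function(x, ...) {
  rts <- vapply(x$spectra, `[[`, numeric(1), "rt")
  cat(sprintf("<lcms_run> %s, %s ESI: %d scans (%.2f-%.2f min), %d MS/MS\n",
              x$label, x$polarity, length(x$spectra),
              if (length(rts)) min(rts) else NA_real_,
              if (length(rts)) max(rts) else NA_real_, length(x$msms)))
  invisible(x)
}

#' Build an extracted-ion chromatogram (EIC)
#'
#' Per spectrum, sums the intensities of all centroids whose ppm error
#' relative to `target_mz` is within `tol_ppm`; 0 where none fall in the
#' window.
#'
#' @param run An [lcms_run()].
#' @param target_mz Target m/z in Da.
#' @param tol_ppm Half-width of the extraction window in ppm.
#' @return An `eic_trace`: list with `target_mz`, `tol_ppm` and parallel
#'   numeric vectors `rt`, `intensity`.
#' @export
build_eic <- function(run, target_mz, tol_ppm = 5) {
  stopifnot(tol_ppm > 0, target_mz > 0)
  half <- target_mz * tol_ppm * 1e-6
  lo <- target_mz - half; hi <- target_mz + half
  n <- length(run$spectra)
  rt <- numeric(n); int <- numeric(n)
  for (i in seq_len(n)) {
    sp <- run$spectra[[i]]
    rt[i] <- sp$rt
    if (length(sp$mz)) {
      j1 <- findInterval(lo, sp$mz) + 1L
      j2 <- findInterval(hi, sp$mz)
      if (j2 >= j1) int[i] <- sum(sp$intensity[j1:j2])
    }
  }
  structure(list(target_mz = target_mz, tol_ppm = tol_ppm,
                 rt = rt, intensity = int),
            class = "eic_trace")
}

# Trapezoidal area under the trace between indices l..r (rt in minutes).
.trapezoid_area <- function(rt, y, l, r) {
  if (r <= l) return(0)
  idx <- l:r
  sum(diff(rt[idx]) * (utils::head(y[idx], -1) + utils::tail(y[idx], -1)) / 2)
}

#' Detect chromatographic peaks in an EIC
#'
#' Local maxima with apex height at or above `min_intensity` are
#' expanded to their flanking valley minima; each surviving peak must
#' pass the S/N and minimum-area gates.  The noise level is
#' 1.4826 x MAD of out-of-peak, non-zero trace values (0 when no such
#' values exist, in which case S/N is Inf).  Area is the trapezoid of
#' the raw trace between the valley bounds.
#'
#' @param trace An [build_eic()] trace.
#' @param constraints A [screening_constraints()] list; uses
#'   `min_intensity`, `sn_min`, `min_peak_area`.
#' @return A data.frame with one row per peak: `rt_apex`, `height`,
#'   `area`, `sn`, `rt_left`, `rt_right`, `shape` (Gaussian fit score in
#'   \[0,1\], advisory).
#' @export
detect_peaks <- function(trace, constraints = screening_constraints()) {
  y <- trace$intensity; rt <- trace$rt
  n <- length(y)
  empty <- data.frame(rt_apex = numeric(0), height = numeric(0),
                      area = numeric(0), sn = numeric(0),
                      rt_left = numeric(0), rt_right = numeric(0),
                      shape = numeric(0))
  if (n < 3L) return(empty)
  apex <- which(y >= c(-Inf, utils::head(y, -1)) &
                  y > c(utils::tail(y, -1), -Inf) &
                  y >= constraints$min_intensity)
  apex <- apex[apex > 1L & apex < n]
  if (!length(apex)) return(empty)
  bounds <- t(vapply(apex, function(i) {
    l <- i; while (l > 1L && y[l - 1L] < y[l]) l <- l - 1L
    r <- i; while (r < n && y[r + 1L] < y[r]) r <- r + 1L
    c(l, r)
  }, numeric(2)))
  # noise from out-of-peak, non-zero trace values; a trace whose
  # candidate apexes are legion is noise-dominated, and the "peaks"
  # themselves then belong in the noise estimate
  in_peak <- logical(n)
  for (k in seq_along(apex)) in_peak[bounds[k, 1]:bounds[k, 2]] <- TRUE
  noise_vals <- if (length(apex) > 10L) y[y > 0] else y[!in_peak & y > 0]
  noise <- if (length(noise_vals) >= 3L) stats::mad(noise_vals) else 0
  peaks <- data.frame(
    rt_apex = rt[apex], height = y[apex],
    area = vapply(seq_along(apex), function(k)
      .trapezoid_area(rt, y, bounds[k, 1], bounds[k, 2]), numeric(1)),
    sn = if (noise > 0) y[apex] / noise else rep(Inf, length(apex)),
    rt_left = rt[bounds[, 1]], rt_right = rt[bounds[, 2]])
  keep <- peaks$sn >= constraints$sn_min &
    peaks$area >= constraints$min_peak_area
  peaks <- peaks[keep, , drop = FALSE]
  if (!nrow(peaks)) return(empty)
  peaks$shape <- vapply(seq_len(nrow(peaks)), function(k)
    shape_score(peaks[k, ], trace), numeric(1))
  rownames(peaks) <- NULL
  peaks
}

#' Gaussian goodness-of-fit score for a peak
#'
#' Fits a Gaussian (apex, center, width) to the trace between the
#' peak's valley bounds by Nelder-Mead least squares from moment-based
#' starting values and returns `max(0, 1 - SS_res / SS_tot)`.  The
#' score is advisory only: it is reported in validation output but
#' never used as an exclusion criterion.
#'
#' @param peak One row of the [detect_peaks()] data.frame (or a list
#'   with `rt_left`, `rt_right`, `rt_apex`, `height`).
#' @param trace The trace the peak was detected in.
#' @return Score in \[0,1\]; degenerate regions (< 4 points or zero
#'   variance) score 0.
#' @export
shape_score <- function(peak, trace) {
  idx <- which(trace$rt >= peak$rt_left & trace$rt <= peak$rt_right)
  if (length(idx) < 4L) return(0)
  x <- trace$rt[idx]; y <- trace$intensity[idx]
  sstot <- sum((y - mean(y))^2)
  if (sstot <= 0) return(0)
  w <- pmax(y, 0)
  mu0 <- if (sum(w) > 0) sum(w * x) / sum(w) else peak$rt_apex
  sd0 <- if (sum(w) > 0) sqrt(sum(w * (x - mu0)^2) / sum(w)) else diff(range(x)) / 4
  sd0 <- max(sd0, min(diff(x)), 1e-6)
  sse <- function(p) {
    if (p[3] <= 0 || p[1] <= 0) return(Inf)
    sum((y - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)))^2)
  }
  fit <- stats::optim(c(peak$height, mu0, sd0), sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  max(0, min(1, 1 - fit$value / sstot))
}

#' Is a sample peak also present in the blank run?
#'
#' Validation step 1: builds the blank's EIC at the same m/z and checks
#' whether a detected blank peak has its apex within `rt_tol_min` of
#' the sample peak's apex.
#'
#' @param sample_peak One row of [detect_peaks()] output for the sample.
#' @param blank_run The blank [lcms_run()] (same polarity).
#' @param target_mz m/z the sample peak was extracted at.
#' @param rt_tol_min Apex retention-time tolerance in minutes.
#' @param constraints A [screening_constraints()] list.
#' @return TRUE if a matching blank peak exists.
#' @export
present_in_blank <- function(sample_peak, blank_run, target_mz,
                             rt_tol_min = NULL,
                             constraints = screening_constraints()) {
  if (is.null(rt_tol_min)) rt_tol_min <- constraints$rt_tol_min
  trace <- build_eic(blank_run, target_mz, constraints$tol_ppm)
  peaks <- detect_peaks(trace, constraints)
  nrow(peaks) > 0 && any(abs(peaks$rt_apex - sample_peak$rt_apex) <= rt_tol_min)
}

#' Serialize an LC-MS run to the internal JSON format
#'
#' @param run An [lcms_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_json <- function(run, path) {
  obj <- list(
    label = run$label, polarity = run$polarity,
    spectra = lapply(run$spectra, function(sp)
      list(rt = sp$rt, mz = sp$mz, intensity = sp$intensity)),
    msms = lapply(run$msms, function(ms)
      list(rt = attr(ms, "rt"), precursor_mz = ms$precursor_mz,
           polarity = ms$polarity, frag_mz = ms$frag_mz,
           frag_intensity = ms$frag_intensity)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an LC-MS run from the internal JSON format
#'
#' @param path Path written by [write_run_json()].
#' @return An [lcms_run()].
#' @export
read_run_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  spectra <- lapply(obj$spectra, function(sp)
    centroid_spectrum(sp$rt, unlist(sp$mz), unlist(sp$intensity),
                      obj$polarity))
  msms <- lapply(obj$msms, function(ms) {
    s <- msms_spectrum(ms$precursor_mz, unlist(ms$frag_mz),
                       unlist(ms$frag_intensity), ms$polarity)
    attr(s, "rt") <- ms$rt
    s
  })
  lcms_run(spectra, obj$label, obj$polarity, msms)
}

#' Read a centroided mzML file as an LC-MS run
#'
#' Thin wrapper over the Bioconductor `mzR` reader for MS1 scans of a
#' single polarity.  Retention times are converted from seconds to
#' minutes.
#'
#' @param path Path to a centroided mzML file.
#' @param label `"sample"` or `"blank"`.
#' @param polarity `"pos"` or `"neg"`; scans of the other polarity are
#'   dropped.
#' @return An [lcms_run()] (MS1 scans only; DDA MS/MS scans are
#'   attached as [msms_spectrum()] objects when present).
#' @export
read_mzml_run <- function(path, label = "sample", polarity = "pos") {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  pol <- .polarity_sign(polarity)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  want_pol <- is.na(hdr$polarity) | hdr$polarity == pol
  ms1 <- which(hdr$msLevel == 1 & want_pol)
  spectra <- lapply(ms1, function(i) {
    pk <- mzR::peaks(fh, i)
    o <- order(pk[, 1])
    centroid_spectrum(hdr$retentionTime[i] / 60, pk[o, 1], pk[o, 2],
                      polarity)
  })
  ms2 <- which(hdr$msLevel == 2 & want_pol)
  msms <- lapply(ms2, function(i) {
    pk <- mzR::peaks(fh, i)
    o <- order(pk[, 1])
    s <- msms_spectrum(hdr$precursorMZ[i], pk[o, 1], pk[o, 2], polarity)
    attr(s, "rt") <- hdr$retentionTime[i] / 60
    s
  })
  lcms_run(spectra, label, polarity, msms)
}
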