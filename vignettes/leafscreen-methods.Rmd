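---
title: "Methods: non-targeted LC-MS toxin screening in leafscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-targeted LC-MS toxin screening in leafscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafscreen)
```

## The screening problem

Non-targeted screening asks: given centroided full-scan LC-MS data of
a complex matrix (here, a plant leaf concentrate), which known toxic
compounds are present? No reference standards are run; identity is
built from converging, individually weak lines of evidence — accurate
mass, isotopic pattern, adduct consistency, chromatographic behaviour,
and data-dependent MS/MS. `leafscreen` implements each evidence layer
as a separate, testable module and combines them with an explicit
confirmation rule.

The pipeline processes one polarity at a time. Its stages are:

1. **Feature discovery** (`find_features`): centroids at or above the
   intensity floor are pooled across scans and clustered in m/z; each
   cluster's extracted-ion chromatogram (EIC) is searched for peaks.
2. **Formula assignment** (`assign_ion`): for each registered adduct,
   every CHNOS formula whose theoretical ion m/z falls within the ppm
   tolerance and whose H/C ratio and DBE fall within the configured
   windows. The enumeration is complete by construction (hydrogen
   counts are bracketed per C/N/O/S cell, and every emitted formula is
   re-checked against the raw predicates); the test suite proves it
   set-equal to a naive grid scan.
3. **Identity**: assigned formulas are looked up in the toxin table;
   each matching record becomes a named candidate. (With vendor
   software this role is played by structure databases; a local table
   is used so the pipeline runs offline and reproducibly.)
4. **Validation checklist** (`validate_candidate`): the per-candidate
   evidence row described below.
5. **Confirmation and merging** (`confirm_toxic`, `merge_polarities`).

## The validation checklist and the confirmation rule

Each candidate yields one row with the fields: retention time,
`not_in_blank`, `above_noise`, `good_peak_shape`, `isotopic_match`
(an adduct label or `"none"`), two database structure-count columns,
and an MS/MS cell (`"no MS/MS"`, `"no match"`, or a hit with a name
and score).

A row is **confirmed** when

> not in blank AND above noise AND isotopic pattern matched AND the
> MS/MS hit is name-consistent with the candidate at a score of at
> least 75%.

Two deliberate asymmetries:

* **Peak shape is advisory.** The checklist reports a Gaussian fit
  score, but a poor shape never vetoes a compound: among the packaged
  checklist fixtures, citric acid carries a flagged shape yet is
  confirmed, so any rule making shape mandatory would contradict the
  recorded outcome. The reported flag lets an analyst re-inspect.
* **Name consistency is mandatory.** A high-scoring library hit on a
  *different* compound (the packaged example: an ethyl cinnamate
  candidate whose best hit is benzyl methacrylate at 61%) is evidence
  against the identity, not for it, and is rejected. Positional
  isomers indistinguishable by MS/MS share an isomer-group label
  (e.g. "3 or 4 methoxybenzaldehyde") and count as consistent with any
  group member.

The confirmation predicate itself is a reconstruction: screening
reports typically print the evidence table and the final list, not
the rule joining them. The conjunction above is the simplest rule
consistent with every row of the packaged fixtures, and it is
threshold-separable — the lowest confirmed score in the fixtures is
80%, the only rejected scored hit is 61%, and the default threshold
75% splits them with margin on both sides. The threshold is a
parameter of `confirm_toxic()`.

## Parameters

All thresholds live in one object, `screening_constraints()`:

| parameter | default | unit | role |
|---|---|---|---|
| `tol_ppm` | 3 | ppm | mass tolerance for formula/ion matching |
| `min_intensity` | 20,000 | counts | chromatographic apex floor |
| `c/h/o/n/s_range` | C 1–90, H 1–190, O 0–18, N 0–5, S 0–1 | atoms | formula search space |
| `hc_min`, `hc_max` | 0.1, 3.5 | — | H/C plausibility window |
| `dbe_min`, `dbe_max` | 0, 40 | — | unsaturation window |
| `sn_min` | 3 | — | chromatographic signal-to-noise gate |
| `min_peak_area` | 1000 | counts·min | peak area gate |
| `mz_min`, `mz_max` | 100, 600 | Da | acquisition window |
| `rt_tol_min` | 0.2 | min | blank-peak apex matching window |
| `shape_min` | 0.8 | — | advisory shape threshold |

The first nine rows are the screening workflow's standard operating
values; the last two are this package's choices. `rt_tol_min` of
0.2 min corresponds to a handful of full scans at typical scan rates —
wide enough to absorb small retention shifts between sample and blank,
narrow enough not to match unrelated blank peaks. The intensity floor
is applied to the *feature apex* (where vendor software applies it),
not to individual centroids.

Ion mass arithmetic uses the proton mass (hydrogen-atom mass minus the
electron mass, 1.00727645 Da) rather than the hydrogen-atom mass: at
m/z 150 a 3 ppm window is 0.00045 Da, the same order as the electron
mass, so the distinction is material. The sodium adduct delta is
likewise electron-corrected. ppm errors are computed on the ion m/z
being matched, since that is how instrument tolerance is specified.

## Isotope patterns

`theoretical_pattern()` convolves per-element isotope distributions
(IUPAC 2013 masses and abundances, embedded as constants so results
are bit-reproducible) on a nominal-mass grid, tracking per-bin
probability and probability-weighted mass so each aggregated
isotopologue gets a centroid m/z. Patterns are computed for the full
ion composition — [M+H]+ gains a hydrogen atom, [M+H−H2O]+ loses O
and H, sodium is treated as monoisotopic — and are aggregated rather
than fine-structured: at 120K resolving power the CHNOS fine structure
below m/z ~400 is not resolved, so the aggregated envelope is what the
instrument records.

`match_pattern()` requires every isotopologue at or above 5% of the
base peak to be observed within the m/z tolerance with a relative
abundance agreeing within ±30%. Both numbers are this package's
choices (configurable): the 5% floor keeps the check meaningful for
carbon-rich formulas without demanding trace isotopologues, and the
±30% band is deliberately loose because ion statistics at low
intensity are poor.

## Chromatography

EICs sum centroid intensities within a ppm window per scan. Peak
detection takes local maxima at or above the apex floor, expands each
to its flanking valley minima, and integrates the raw trace by
trapezoid between the bounds (no baseline subtraction — the simplest
reproducible reading of a minimum-area rule). The noise level is
1.4826 × MAD of out-of-peak, non-zero trace values, a robust estimate
that ignores both the peaks themselves and the empty regions of a
sparse trace; S/N is apex height over that estimate. Two documented
edge cases:

* a trace with no non-zero out-of-peak values (a clean spike in an
  otherwise empty window) has noise 0 and S/N = Inf;
* a trace with more than 10 candidate apexes is noise-dominated, and
  the noise estimate then includes the "peaks" themselves — otherwise
  dense noise would mask its own variance by claiming every point as
  peak territory.

Zero-valued padding never changes the result (tested), so runs of
different lengths compare cleanly.

The shape score fits a three-parameter Gaussian to the peak region by
Nelder–Mead least squares from moment-based starting values and
reports `max(0, 1 − SS_res/SS_tot)`; regions with fewer than four
points or zero variance score 0.

## MS/MS matching

Spectra are normalized to base fragment 1. Similarity is the squared
cosine of √-intensity fragment vectors after greedy pairing —
query fragments in decreasing intensity order each claim the unused
reference fragment with the smallest |ppm| within tolerance — which
equals `100 · (Σ√(qᵢrᵢ))² / (Σq · Σr)`. Removing one of three
equal-intensity fragments therefore scores 66.7%, self-match scores
100, and the measure is symmetric and scale-invariant. The √-intensity
weighting is standard spectral-library practice (it de-emphasizes the
base peak's dominance); a plain-intensity variant is selectable.
Fragment tolerance defaults to 10 ppm — looser than the 3 ppm
precursor tolerance because fragments from an ion-trap are less
accurate than orbitrap full-scan masses. When two or more entries
within one score point of the top hit share an isomer group, the group
label is reported instead of an arbitrary member.

## The toxin table

The packaged `toxins.csv` is a miniature hazard table in the
OpenFoodTox mould: canonical name, pipe-delimited synonyms, formula,
and a free-text hazard note, covering every compound in the packaged
checklist fixtures plus 22 decoy toxins that the fixtures must *not*
match. A user-supplied full hazard export loads through the same
strict-header reader. Name matching is case-, whitespace- and
punctuation-insensitive but stereo-sensitive by default (L-, D-, DL-
prefixes distinguish records), with an optional collapse mode — name
ambiguity cuts both ways, and the default errs toward not conflating
enantiomers. Named candidates match by name or synonym only; formula
matching is a fallback for name-less candidates, so a decoy sharing a
formula with a toxin never piggy-backs in by mass alone. Two packaged
compounds (an organophosphate and a phosphine oxide) contain P/Cl and
fall outside the CHNOS formula domain; their records carry an empty
formula and participate in name matching only.

## The synthetic-run generator

`simulate_run()` emulates the screening acquisition: 30-minute runs
(the packaged chromatograms contain no later peaks), centroid full
scans over m/z 100–600 in a single polarity, and data-dependent MS/MS
on the five tallest precursors per scan with 0.5 min dynamic
exclusion. Each spike contributes a Gaussian elution profile carrying
its complete isotopologue envelope; every true centroid receives
uniform mass error within ±2 ppm — uniform rather than Gaussian so
that no ground-truth ion can ever leak outside the 3 ppm gate, which
keeps recovery tests sharp rather than probabilistic. Noise centroids
are Poisson(40) per scan at uniform m/z with exponential intensities
(mean 2000, an order of magnitude below the apex floor). The default
scan interval is 0.03 min and the default peak width σ = 0.08 min,
desk-scale choices that put ~10 scans across a peak; the packaged
spike sets place the eight confirmed toxics at their reported
retention times with apexes between 2×10⁵ and 10⁶ counts, and spike
salicylic acid into the negative-mode blank as the
contaminant-rejection control.

What the generator does *not* emulate — and what passing tests
therefore do not demonstrate about real data: real fragmentation
chemistry (library and query spectra come from the same deterministic
pseudo-fragment generator, so MS/MS tests exercise the matching
machinery, not compound identification), retention-time drift between
sample and blank, chimeric co-elution within an isolation window,
detector saturation, and electrospray matrix effects. The generator
answers "does the pipeline recover what was put in, under the stated
noise model?", not "would the instrument see it?".

`make_library()` derives each compound's spectrum from a seeded hash
of its name (or isomer-group label, so group members share a spectrum
exactly); both the generator and the simulator restore the caller's
RNG state, and a fixed seed yields bit-identical runs.

## Numerical choices and degenerate inputs

* Candidate ordering is |ppm| ascending, ties by lower DBE, then Hill
  string — a reporting convention of this package, chosen so output is
  deterministic; no scientific weight is attached.
* Hydrogen bracketing in the enumerator uses ±1e-9 guards around
  ceiling/floor so floating-point edges cannot drop a boundary
  formula; the final exact re-check guarantees soundness regardless.
* An empty formula has mass 0 and is the identity for formula
  addition; H/C is an error (not 0/0) for carbon-free formulas.
* `enumerate_formulas` on a mass below the lightest admissible formula
  returns an empty frame, not an error; `assign_ion` outside the
  acquisition window *is* an error, since it indicates a unit mistake.
* A missing blank run is a configuration error: checklist step 1 is
  mandatory and silently skipping it would bias toward confirmation.
* Evidence absence ("no MS/MS") is recorded, never raised.

## Limitations

* Elements beyond CHNOS (P, Cl, Br, …) are out of scope; compounds
  containing them can be name-matched but not formula-assigned.
* Only singly charged ions are considered.
* The adduct registry ships the four forms seen in the packaged
  fixtures; others can be registered but start untested.
* The database structure-count columns are annotations from packaged
  fixtures, not live queries, and carry no confirmation weight.
* Confirmation reproduces a reconstructed rule; analysts applying
  different evidence policies should treat `confirm_toxic()` as one
  defensible default, not a standard.
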