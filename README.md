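# leafscreen

Non-targeted LC-MS screening for toxic compounds in plant leaf
concentrates.

Leaf concentrate — the protein-rich coagulate pressed from blended,
heat-treated leaves — is a candidate emergency and alternative food,
but the toxin content of most tree leaves is unknown. `leafscreen`
re-implements, as an open and fully tested pipeline, the non-targeted
screening workflow used to assess red maple leaf concentrate with
high-resolution ESI LC-MS: detect chromatographic features, assign
elemental formulas to accurate masses, gather isotope-pattern and
MS/MS evidence, cross-reference identities against a food-toxin hazard
table (OpenFoodTox-style), and apply a formula-validation checklist to
arrive at a confirmed toxic-compound list. It is aimed at analysts who
have centroided full-scan data (with optional data-dependent MS/MS)
and want a reproducible, scriptable alternative to vendor software for
this class of screen.

## The method

For every observed ion m/z the pipeline enumerates **all** CHNOS
formulas that explain it, under the screening constraint set:

* mass tolerance 3 ppm; minimum apex intensity 20,000 counts;
* element ranges C(1–90) H(1–190) O(0–18) N(0–5) S(0–1);
* 0.1 ≤ H/C ≤ 3.5 and 0 ≤ DBE ≤ 40, where
  DBE = C − H/2 + N/2 + 1;
* adducts [M+H]+, [M+H−H2O]+, [M+Na]+ in positive mode and [M−H]− in
  negative mode, with electron-corrected mass deltas;
* acquisition window m/z 100–600, chromatographic gates S/N ≥ 3 and
  peak area ≥ 1000.

Candidates anchored to a detected peak then pass through the
validation checklist: (1) absent from the paired blank run, (2) above
noise (apex, S/N and area gates), (3) Gaussian peak-shape score
(advisory only — a compound may be confirmed with a flagged shape),
(4) theoretical isotopologue pattern observed in the spectrum,
(5)–(6) database structure-count columns (carried through as
annotations), and (7) an MS/MS library hit, scored as the squared
cosine of √-intensity fragment vectors, that is *name-consistent* with
the candidate (isomer groups such as 3-/4-methoxybenzaldehyde count as
consistent) at a score ≥ 75%. Confirmed compounds from both polarities
are merged by normalized name.

A deterministic synthetic-run generator (`simulate_run()`) produces
paired sample/blank runs with known ground truth — Gaussian elution,
full isotopologue envelopes, ±2 ppm mass error, Poisson noise, top-5
DDA with dynamic exclusion — so the entire pipeline is testable
without instrument data.

## Worked example

Simulate both polarities with the packaged spike sets (the eight
confirmed leaf-concentrate toxics, plus salicylic acid spiked into the
blank as a contaminant control) and screen them against the packaged
toxin table:

```r
library(leafscreen)
res <- screen_synthetic(seed = 7)
res$report
#> <screening_report> 5 positive-mode rows (5 confirmed), 5 negative-mode rows (4 confirmed), 8 toxic compounds total
#> confirmed toxic compounds:
#>   3-Methoxybenzaldehyde        (pos)
#>   4-Methoxybenzaldehyde        (pos)
#>   Coumarin                     (pos)
#>   L-Glutamic acid              (both)
#>   L-Phenylalanine              (pos)
#>   L-Aspartic acid              (neg)
#>   Citric acid                  (neg)
#>   Naringin                     (neg)
```

Eight compounds are confirmed; L-glutamic acid was found in both
polarities and is merged into a single entry. The blank contaminant is
detected but rejected at checklist step 1, even though every other
evidence item is strong:

```r
res$report$neg_rows[res$report$neg_rows$name == "Salicylic acid", ]
#>             name    rt not_in_blank above_noise isotopic_match          msms
#> 2 Salicylic acid 21.72        FALSE        TRUE          [M-H] Salicylic ...
```

The same machinery works on real data: read runs with
`read_mzml_run()` (or `read_run_json()`), a hazard table with
`read_toxin_db()`, a spectral library with `read_msms_library_json()`
or `read_msms_library_msp()`, then call `screen_run()`,
`screening_report()` and `render_report()`. The installed
`exec/leafscreen` script wraps this as a shell command
(`leafscreen run --sample-pos ... --blank-pos ... --toxdb ...
--library ... --out ...`); `leafscreen validate-fixtures` replays the
packaged checklist fixtures and exits 0 only when all counts check
out.

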