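Package: leafscreen
Title: Non-Targeted LC-MS Screening for Toxic Compounds in Leaf Concentrates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An open, tested re-implementation of a non-targeted
    LC-MS screening workflow for toxic compounds in plant leaf
    concentrates.  Covers chromatographic peak detection with
    signal-to-noise and area thresholds, exhaustive CHNOS molecular
    formula assignment under a ppm mass tolerance with H/C and
    double-bond-equivalent constraints, theoretical isotopologue
    pattern simulation and matching, MS/MS spectral library cosine
    matching, cross-referencing against a food-toxin hazard table,
    and the formula-validation checklist that yields the final
    confirmed toxic-compound list.  Includes a deterministic
    synthetic LC-MS run generator with known ground truth so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
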