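Package: tmedyn
Title: Paired Pre/Post-Therapy Tumor-Microenvironment Dynamics from Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for paired pre-/post-therapy single-cell tumor
    microenvironment cohorts: cell-type enrichment scores, signed
    regression-based predictive and therapeutic indices (Pi/Ti) relating
    cell-population features to tumor-size change, sample-level cluster
    occupancy, TCR clonotype expansion/contraction classification by
    Fisher's exact test with D50 repertoire diversity, gene-signature
    exhaustion and cytotoxicity scoring with control-derived background
    cutoffs, ligand-receptor edge specificity weighting, and bulk-cohort
    marker-score validation with median-split log-rank survival analysis.
    Includes a seeded synthetic-cohort generator with planted
    compositional, clonal, and expression effects so every stage is
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
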