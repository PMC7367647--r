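Package: cinscreen
Title: Chromosomal Instability Screening from Low-Pass Plasma cfDNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects chromosomal instability in plasma cell-free DNA from
    low-pass whole-genome sequencing. Reads are counted in fixed 200 kb bins,
    converted to per-bin Z-scores against a reference panel of healthy
    controls, segmented with a from-scratch circular binary segmentation
    (CBS) implementation with permutation significance, and scored against a
    packaged 29-segment liver-cancer panel at an optimized Z cutoff (2.702)
    to produce a positive/negative screening call. Includes cohort-level
    evaluation (sensitivity/specificity, ROC/AUC, exact Fisher association
    tests, combined-marker positivity), longitudinal segment tracking, and a
    seeded negative-binomial cfDNA simulator with known copy-number truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Rsamtools,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
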