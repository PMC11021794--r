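Package: helmamp
Title: Single-Cell and Population-Level Analysis of Nematode Antimicrobial
    Peptide Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the action of helminth-derived
    antimicrobial peptides on bacteria across scales: a continuous-time
    stochastic simulator of mother-machine trenches (single-file bacterial
    lineages with exponential elongation, sizer division, Poisson lysis and
    open-end eviction), dynamic-programming lineage tracking from per-frame
    cell observations, single-cell growth-rate and lysis-frequency
    estimation, a deterministic birth-death population model linking
    single-cell effects to bulk colony counts, Miles-Misra CFU assay
    analysis with one-way ANOVA and Tukey comparisons, and peptide
    physicochemistry (net charge, isoelectric point, composition, molar
    extinction, structure-based disulfide detection) with consensus
    screening of antimicrobial-peptide candidate score tables.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
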