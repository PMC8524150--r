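Package: stopchange
Title: Simulation and Analysis of the STOP-CHANGE Paradigm with
    Immediate-Early-Gene Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for cross-species studies of multi-component behavior
    with the STOP-CHANGE paradigm. Simulates the task for human and pigeon
    variants with a 1-up/1-down stop-signal-delay staircase and a generative
    race-model agent spanning the serial-to-parallel processing continuum;
    computes stop-signal reaction times (mean method) and the SCD-RT2 slope;
    quantifies immediate-early-gene (ZENK/egr-1) positive cells on section
    micrographs by intensity-band particle detection with size and roundness
    filters and standardises counts to cells per square millimetre; and runs
    the accompanying inferential statistics (Welch/Student t-tests with
    Bonferroni-adjusted alphas, mixed-design repeated-measures ANOVA with
    partial eta squared, Spearman correlation with exact small-n p-values,
    and a BIC-approximate Bayes factor for the null).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
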