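Package: srmflow
Title: Multiplexed SRM Assay Design, Scheduling and Quantification for
    Monitoring Neural Stem-Cell Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A workflow for multiplexed selected reaction monitoring (SRM)
    of protein markers across a cell-differentiation time course: in-silico
    tryptic digestion and proteotypic peptide selection, light/heavy
    precursor and b/y fragment m/z calculation, transition enumeration and
    panel validation, indexed-retention-time (iRT) calibrated acquisition
    scheduling with dwell/cycle-time feasibility checks, transition-level
    quantification with signal-to-noise filtering, below-background
    imputation, median-of-transition peptide abundances,
    detectable/quantifiable protein calls, mixed-effects condition-versus-
    control log2 fold-changes with Benjamini-Hochberg FDR control, qPCR
    delta-Ct normalisation and protein-mRNA correlation, and a synthetic
    time-course generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
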