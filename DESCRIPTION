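Package: constraintkit
Title: Gene Constraint, Loss-of-Function Annotation and Literature
    Integration for Population-Scale Exome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators and models for gene constraint analysis at
    population scale: mutational saturation and infinite-sites recurrence
    under recurrent mutation, analytic observed/expected theory and LOEUF
    (loss-of-function observed/expected upper bound fraction) statistics
    with simulation-based power, a Bayesian mixture model jointly inferring
    heterozygous selection coefficients and per-variant probabilities of
    neutrality from allele frequencies, an NMD-informed rule engine for
    loss-of-function variant classification with data-driven threshold
    calibration, a beta-binomial mixture model for allelic-expression
    signatures of nonsense-mediated decay, Bayesian integration of
    literature-derived gene scores with constraint counts, and shared
    benchmarking statistics. Includes a synthetic-exome simulator for
    allele counts under mutation-selection-drift with recurrent mutation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
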