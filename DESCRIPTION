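Package: grsmr
Title: Genetic Risk Score Mendelian Randomization for Binary Outcomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Weighted allele-score (genetic risk score) Mendelian
    randomization for case-control outcomes. Builds a per-individual
    relative-exposure score from GWAS summary weights after allele
    harmonization, estimates causal odds ratios per SD of the exposure by
    logistic regression with a parametric bootstrap correction for
    instrument-weight imprecision, pools stratum-level estimates by
    DerSimonian-Laird random-effects meta-analysis with I2 heterogeneity
    and Higgins-Thompson confidence intervals, and provides leave-one-out
    and all-subsets instrument sensitivity analyses, instrument-confounder
    balance diagnostics, analytic power calculations, and a calibrated
    case-control cohort simulator for end-to-end validation. Ships the
    five-variant 25-hydroxyvitamin D instrument as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
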