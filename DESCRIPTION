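Package: g7ps
Title: Galectin-7 Prediction Score Pipeline for Chemoradiotherapy
    Resistance in Oral Squamous Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free LC-MS biomarker screening and immunohistochemistry
    scoring pipeline for predicting chemo- and/or radiotherapy resistance in
    oral squamous cell carcinoma. Implements peak alignment and normalization
    of per-run peak lists, a staged Mann-Whitney/ROC/annotation/ratio
    filtering funnel, stepwise linear discriminant marker selection by Wilks'
    lambda, DAB stain separation with stained-area (G7S) and nuclear-fraction
    (G7N, G7NL) quantification, the linear galectin-7 prediction score (G7PS)
    with confusion-matrix evaluation and Youden-optimal cutoffs, Kaplan-Meier
    and log-rank survival stratification, and synthetic data generators for
    every stage. Ships the 86-patient cohort and 20-peptide differential peak
    tables as machine-readable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
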