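Package: synerscreen
Title: Drug-Combination Synergy Screening Analysis for Patient-Derived Tumor Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for high-throughput drug-combination viability
    screens on patient-derived tumor cell cultures. Provides plate-level
    normalization to no-drug controls, Hill-equation dose-response fitting with
    IC50 censoring and normalized AUC scoring, exact Gaussian-process modelling
    of 7x7 combination dose-response surfaces with iso-effect contour
    extraction, Chou-Talalay Combination Index and Bliss-beta synergy scoring
    with optimal-regimen identification, empirical-Bayes moderated t-tests for
    reverse-phase protein array (RPPA) differential-affinity analysis with
    Benjamini-Hochberg FDR control, tumor-growth summaries for patient-derived
    xenograft (PDX) experiments, and seeded synthetic-data generators that
    emit every input the pipeline consumes together with its ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
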