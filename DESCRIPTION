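Package: reimsfp
Title: REIMS Fingerprint Classification of Faecal Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for phenotype classification from rapid
    evaporative ionisation mass spectrometry (REIMS) burn spectra of rodent
    faecal pellets. Covers simulation of negative-ion scan series with
    lipid-like isotope-resolved peak profiles, burn-event detection and
    aggregation, single-point lockmass recalibration, fixed-grid spectral
    binning and total-ion normalisation, per-individual averaging,
    PCA-seeded discriminant function analysis, random-forest classification
    with out-of-bag and split evaluation, label-randomisation null tests,
    permutation-importance ranking of discriminant m/z bins, and isotopomer
    cross-correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    MASS
Config/testthat/edition: 3
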