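Package: thioltrace
Title: Diagnostic-Fragment Screening and Targeted Quantification of
    Derivatized Thiols by LC-MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational workflow for charge-tagged thiol metabolomics by
    liquid chromatography tandem mass spectrometry. Implements monoisotopic
    mass and adduct arithmetic for a triphenylphosphonium derivatization
    probe, screening of MS2 spectra for the shared diagnostic fragment ion
    of labeled thiols with compound-library annotation, internal-standard
    calibration with limit-of-detection, precision and spike-recovery
    arithmetic, cohort-level differential statistics (fold changes, t-tests,
    NIPALS partial least squares discriminant analysis with S-plot, z-scored
    heatmap clustering, volcano analysis), repeated stratified train/test
    evaluation of random-forest and ridge logistic-regression classifiers,
    and seeded generators for synthetic MS2 runs, calibration series and
    cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    randomForest,
    glmnet,
    mzR
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
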