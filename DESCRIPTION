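Package: rtvarlab
Title: Experimental Variability in LC-MS Proteomics and Its Impact on
    Retention-Time Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@rtvarlab.org",
           role = c("aut", "cre"))
Description: Tools to study how experimental variability in liquid
    chromatography-mass spectrometry (LC-MS) proteomics propagates into
    machine-learned retention-time predictors. Provides a hierarchical
    simulator of multi-project LC-MS corpora (gradient-length multimodality
    with within-project homogeneity, m/z acquisition-window conventions,
    additive-coefficient peptide elution with project/file/peptide variance
    components, MS2 spectra with backbone and single-residue fragment ions);
    per-file metadata variability statistics; stratified dataset construction
    with effective-gradient (iRT-like) normalization and leakage-safe splits;
    a bidirectional-GRU-with-attention retention-time regressor with transfer
    learning and Monte-Carlo-dropout uncertainty; and MS2 peak-density and
    single-residue fragment-ion analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
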