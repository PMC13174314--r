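Package: regenmac
Title: Macrophage Metabolic and Signaling Analysis for Regenerative Digit Injuries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for identifying a spatially restricted,
    BMP-ligand-expressing, fatty-acid-oxidation-biased macrophage population
    that distinguishes regenerative (P3) from fibrotic (P2) mouse digit
    injuries. Provides bin-matched control gene-set module scoring,
    Wilcoxon marker-signature derivation, glycolysis-versus-FAO metabolic
    state statistics with variance partitioning and Kolmogorov-Smirnov
    comparison, signature-based spatial spot classification with
    conditional pathway scoring, permutation-scored ligand-receptor
    communication, PCA and OPLS-DA with VIP for metabolomics,
    extracellular-flux trace metrics and qPCR relative expression, plus a
    seeded synthetic-data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    multcomp
Suggests:
    withr,
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    png,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
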