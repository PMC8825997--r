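Package: derepms
Title: Dereplication and Chemometric Profiling of LC-HRMS Metabolomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adduct-aware dereplication of liquid chromatography high-resolution
    mass spectrometry (LC-HRMS) peak lists against natural-product compound
    libraries, with supporting tools for molecular-formula enumeration under
    ppm tolerance, cross-polarity feature merging, multivariate chemical
    profiling (Pareto scaling, PCA with cross-validated Q2, sparse PLS-DA with
    VIP scores, hierarchical clustering and ANOVA-selected heatmaps), and
    dose-response cytotoxicity summarisation (MTT viability, four-parameter
    logistic IC50, unpaired t-tests). Ships a 40-record mini-library of
    Streptomyces secondary metabolites and a synthetic-data generator that
    emulates multi-extract dual-polarity acquisitions with planted ground
    truth, so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    yaml,
    minpack.lm,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    mzR,
    optparse
Config/testthat/edition: 3
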