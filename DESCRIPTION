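Package: pfascf
Title: Freshwater Ecotoxicity Characterization Factors for PFAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes freshwater ecotoxicity characterization factors (CFs)
    for per- and polyfluoroalkyl substances (PFAS) in the USEtox tradition.
    Provides a four-step harmonization of raw aquatic ecotoxicity records
    (CAS validation, reliability screening, qualifier/species/unit/duration
    standardization, deduplication), species-sensitivity-distribution effect
    factors based on HC20 (chronic EC10 equivalents) and HC50 (chronic EC50
    equivalents), freshwater fate and exposure factors under standard
    Kow-derived and PFAS-adapted Koc-based partitioning, assembly of CFs for
    the four methodology combinations, log-space regression comparisons, and
    a group analysis by number of perfluorinated carbons. Ships a synthetic
    data generator with known ground truth so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
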