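Package: ptmlipidr
Title: Differential PTM-Site Quantification and Lipidomics Class Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for label-free and TMT differential
    analysis of post-translational modification (PTM) sites and for targeted
    lipidomics. PTM-site intensities are centralized into relative quantitative
    values, optionally normalized by host-protein abundance, and called
    differential with a replicate-ratio fold change plus a coefficient-of-
    variation significance filter. Metabolite peak-area tables are analysed by
    OPLS-DA with VIP scores, cross-validated Q2 and permutation validation,
    fold-change calling, lipid-class summarization, and a three-group
    control/stress/rescue reversal analysis. A seeded synthetic-data generator
    emulates the assumed data structure (log-normal protein baselines,
    occupancy-scaled site intensities, multiplicative replicate noise, missing
    values, TMT ratio compression, class-structured metabolite effects) so the
    whole chain is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
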