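Package: preannotate
Title: Pre-Annotation of LC-MS Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organizes untargeted LC-MS metabolomics features into putative
    compounds prior to identification. Detects 13C/12C isotopic pairs and
    estimates a study-specific retention-time coelution window, assembles
    coeluting features into khipu grids of isotopologues and adducts with
    inferred neutral masses, discovers recurrent mass differences between
    coeluting features to nominate candidate in-source fragments, screens
    feature tables against MS/MS spectral libraries for fragment co-detection,
    and stratifies annotation coverage by feature abundance. Includes a
    synthetic feature-table generator with planted ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
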