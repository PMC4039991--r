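Package: steroidscreen
Title: Marker-Anchored Single-Cell Co-Expression Screening, Pathway
    Completeness Scoring, and Dye-Dilution Proliferation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterising steroidogenic
    suppressor subpopulations in T helper cells from expression data.
    Implements pathway-completeness scoring of steroidogenesis gene
    expression (how far along the cholesterol-to-pregnenolone chain a
    condition can proceed), a marker-anchored single-cell Spearman
    correlation screen with gene-module and cell clustering and
    surface-marker nomination, single-cell qPCR Ct normalisation,
    dye-dilution generation deconvolution with division-index and
    suppression-assay quantification, and seeded synthetic-data
    generators with planted ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
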