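Package: optica
Title: Optimal Dimensionality Selection for Independent Component
    Analysis of Expression Compendia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decomposes gene-expression compendia with robust
    multi-restart independent component analysis (ICA) across a grid of
    dimensionalities, tracks how components are conserved across
    dimensions via a dimensionality tree, classifies components
    (single-gene, regulatory, conserved) using regulon enrichment, and
    selects the optimal ICA dimensionality as the point where the number
    of non-single-gene components equals the number of conserved
    components.  Includes principal-component cumulative-variance and
    stability-based baseline selectors, a ground-truthed synthetic
    compendium generator, tidy summaries and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
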