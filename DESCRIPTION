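Package: droughtscreen
Title: Drought-Tolerance Screening of Forage Grass Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of greenhouse drought-screening trials for
    forage grasses laid out as a randomized complete block split-plot design
    (water regime on whole plots, ecotype on sub-plots). Provides validated
    readers for long- and wide-format trait tables, trait summaries
    (mean +/- SEM), relative water content and signed stress-response
    percentages, split-plot analysis of variance with the correct error
    strata, LSD mean separation and CV%, the seven classical yield-based
    drought-tolerance indices (MP, GMP, TOL, YSI, YI, SSI, STI), trait
    correlation matrices, standardized principal component analysis with a
    contribution-weighted genotype ranking value, agglomerative hierarchical
    clustering with cluster profiling, and a seeded synthetic split-plot
    trial generator with known tolerance classes for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
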