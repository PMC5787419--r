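Package: aagci
Title: Age-Associated Gene Co-Expression Screening via Liquid Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene pairs whose co-expression changes with a quantitative
    scouting variable (typically donor age) using the liquid-association score on
    inverse-normal transformed expression data. Pairs are screened within
    functional gene-set modules (GO/KEGG-style GMT collections), significance is
    assessed by a permutation test with a normal approximation to the null, and
    discoveries are controlled by Benjamini-Hochberg adjustment within modules.
    Downstream stages compare liquid-association pairs with ordinary Pearson
    co-expression, find key-driver genes whose protein-protein interaction
    neighbourhoods are enriched for age co-expressed genes, test overlap with
    curated aging-gene lists, and rank drug or gene perturbation signatures that
    may reverse age-directional expression changes. A synthetic-data module
    generates studies with known planted structure so every stage is testable
    without controlled-access data.
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
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
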