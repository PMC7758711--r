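Package: ecoevo
Title: Eco-Evolutionary Analysis of Metabolic Evolution in Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for experimental-evolution studies of a
    focal bacterial species evolving in model decomposer communities.
    Implements phenotypic trajectory analysis of multivariate substrate-use
    phenotypes (path length, direction and shape, tested by randomization of
    residuals in a permutation procedure), mutational-parallelism inference
    from clone variant tables via Jaccard similarity with permutational
    ANOVA, Bray-Curtis community-phenotype covariance analyses, and
    Malthusian growth-rate statistics, together with a seed-reproducible
    synthetic-data generator emulating the data shapes of such experiments
    so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
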