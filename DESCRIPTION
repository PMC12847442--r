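Package: stoichnet
Title: Ecoenzymatic Stoichiometry Vectors and Microbial Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for soil microbial nutrient limitation along
    agricultural management gradients. Computes extracellular enzyme C:N:P
    stoichiometry ratios and vector length/angle statistics with the 45-degree
    nitrogen/phosphorus limitation rule, alpha diversity (bias-corrected Chao1,
    Shannon, Gini-Simpson) and rarefaction, Bray-Curtis distances, correlation
    threshold co-occurrence networks with topology summaries and GraphML export,
    permutation Mantel tests, balanced two-way ANOVA (raw or summary-statistics
    mode), Duncan's multiple range letters, and a synthetic study generator with
    planted correlation blocks for end-to-end validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
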