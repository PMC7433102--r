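Package: sdsclim
Title: Sex-Determination Systems and Breeding-Season Climate in Reptiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic comparative analysis linking reptile sex-determination
    systems (temperature-dependent versus genotypic) to the climate of their
    breeding seasons. Provides breeding-window climate statistics (median
    ambient value, within-year seasonality, interannual fluctuation) over
    gridded monthly climate and species range masks, a consecutive-month
    randomization null for window placement, phylogenetic generalized least
    squares under Ornstein-Uhlenbeck and Pagel's lambda correlation structures
    with range-area weights and variance-heterogeneity likelihood-ratio tests,
    Firth-penalized phylogenetic logistic regression, Pagel's lambda
    phylogenetic signal, d-separation phylogenetic path analysis with CICc
    ranking and full-model averaging, and a synthetic-study generator (birth-
    death trees, Mk binary traits conditioned on a transition count, seasonal
    climate grids, range blobs, breeding windows, OU traits) so the entire
    pipeline runs and is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    phytools,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
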