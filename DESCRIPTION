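Package: eaccd
Title: Ordered Prognostic Grouping of Censored Survival Data by Ensemble
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds ordered prognostic grouping systems from censored
    survival data stratified into prognostic-factor combinations.
    Implements the Ensemble Algorithm for Clustering Cancer Data (EACCD):
    a Mann-Whitney effect-size dissimilarity computed on Kaplan-Meier
    curves completed with exponential tails, ensemble dissimilarity
    learning from repeated Partitioning Around Medoids runs, minimax
    linkage hierarchical clustering, and knee-point selection of the
    number of groups on a Harrell C-index curve.  Includes internal and
    temporal validation tools (adjacent-group Cox and logrank
    comparisons, a correlated C-index difference test, contingency and
    rank-correlation comparison of two grouping systems) and a
    registry-like cohort simulator with planted group structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
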