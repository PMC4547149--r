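Package: mirtarget
Title: miRNA Target Prediction from Paired miRNA-mRNA Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts microRNA (miRNA) targets from matched miRNA and mRNA
    expression profile data and lays out the resulting bipartite regulatory
    network. Implements the load-filter-predict-visualize pipeline:
    differential-expression filtering (paired/Welch t-tests, signed fold
    change), expression-based association scoring (Pearson/Spearman
    correlation, the Kraskov-Stoegbauer-Grassberger k-nearest-neighbour
    mutual-information estimator, and the maximal information coefficient),
    variational-Bayes scoring of candidate pairs under a GenMiR++-style
    down-regulation model, sequence-database candidate lookup, cross-algorithm
    intersection into an interaction table, and network layouts (circular,
    force-directed, Kamada-Kawai, a modified inverted self-organizing-map
    layout, and a two-level squarified treemap). A seeded synthetic-data
    generator with planted regulation supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
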