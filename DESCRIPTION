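Package: cpann
Title: Supervised Self-Organizing Maps for Binary QSAR Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counter-propagation artificial neural networks (CPANN) and
    related supervised self-organizing-map classifiers for tabular
    molecular-descriptor data, including the X-Y fused network with
    adaptive learning and two damped-update CPANN variants that improve
    cluster formation on the response surface.  Provides a clustering
    formation score with a permutation baseline for judging response-surface
    cluster quality, genetic-algorithm selection of descriptor subsets and
    training hyperparameters under four fitness criteria, a stability-based
    model-screening pipeline with external validation, descriptor filtering
    and normalization utilities, SOM-stratified set splitting, and a seeded
    generator of synthetic descriptor datasets with planted class structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
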