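Package: genomni
Title: Generalized Omnibus Embedding of Correlated Random Dot Product Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint spectral embedding of collections of random dot product
    graphs (RDPGs) on a shared vertex set via generalized omnibus matrices.
    Provides samplers for edge-correlated graph collections (forward-
    propagation chains and single-generator families), a family of omnibus
    weight designs (classical, total-average, weighted pairwise, dampened,
    forward, pair-preserving), closed-form calculators for the limiting
    induced and inherent correlation of the embedded latent-position
    estimates and for effective sample size under edge correlation,
    empirical edge-correlation estimators, and simulation pipelines for
    community detection and network time-series change-point analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
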