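Package: modima
Title: Multivariate Omnibus Distance Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distance-based mediation testing for multivariate
    exposure-mediator-response triples. Implements the MODIMA test
    statistic, the product of the distance correlation between exposure
    and mediator and the partial distance correlation between mediator
    and response given the exposure, with an adaptive permutation test;
    the univariate product-of-correlations single-mediator baseline; the
    energy-statistics primitives (double and U-centering, distance
    covariance and correlation, bias-corrected distance correlation,
    partial distance correlation); beta-diversity dissimilarities
    (Bray-Curtis, Jaccard, Jensen-Shannon divergence, unweighted,
    weighted and generalized UniFrac over a rooted tree); and simulation
    machinery for type-I-error and power studies, including a
    single-mediator linear model and Dirichlet-multinomial microbiome
    mixture mediators on random rooted trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vegan
Suggests:
    optparse,
    phyloseq,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
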