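Package: wmstream
Title: Working-Memory Biases in Sequential Perceptual Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for psychophysical experiments in which observers
    judge the color composition of a stream of random-dot displays while holding
    the color and location of a sample in visual working memory. Implements
    pixel-wise logistic reverse correlation (spatiotemporal decision-weight maps
    with an unbiased-observer baseline and false-discovery-rate corrected group
    maps), rotational alignment to the memorized location with pie-segment
    angular tuning and rotation-baselined map stability, psychometric choice
    models with additive working-memory color-bias terms and recency slopes, and
    bidirectional memory-perception crosstalk statistics. A synthetic-experiment
    generator produces task stimuli and parameterized observers so that every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
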