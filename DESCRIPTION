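Package: escbn
Title: Bayesian Network Analysis of Metro Escalator-Related Injuries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probability and severity analysis of metro
    escalator-related injuries with discrete Bayesian networks. Fuses
    expert opinions on candidate causal arcs with Dempster-Shafer evidence
    combination, arbitrates uncertain arcs by mutual information and prunes
    the network with conditional-independence tests, learns conditional
    probability tables from incomplete incident records with an
    expectation-maximization algorithm, and reports evidence-conditioned
    posterior tables by exact variable-elimination inference. Includes a
    calibrated synthetic generator of incident records so that every stage
    of the pipeline can be exercised and validated without access to
    proprietary metro incident registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
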