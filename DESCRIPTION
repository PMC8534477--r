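Package: camap
Title: Constraint-Adjusted MAP Estimation of Bayesian Network Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns conditional probability tables of discrete Bayesian
    networks from small complete datasets together with qualitative expert
    knowledge expressed as parameter constraints (ranges, within-row
    orderings, and monotonic-influence orderings across parent
    configurations). An informative Dirichlet prior is elicited by uniform
    hit-and-run sampling of the constraint polytope, lower bounds on the
    equivalent sample size (ESS) are derived from the constraints, and
    global and local ESS values are selected by cross-validation. Includes
    maximum-likelihood, uniform-prior MAP, maximum-entropy and constrained
    maximum-likelihood/entropy baselines, forward sampling, exact joint
    Kullback-Leibler evaluation, BIF and JSON network I/O, and a synthetic
    benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
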