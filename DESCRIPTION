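Package: dosesearch
Title: Diverse Stochastic Search for Optimal Drug-Combination Doses
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequential design of drug-combination experiments on a
    discretized concentration grid. Implements the diverse stochastic
    search (DSS) algorithm: a maximin Latin-hypercube initialization
    phase followed by an iterative segment that alternates, at random,
    between a focused hill-exploring search and a diverse Gibbs-sampled
    exploration of a response surface estimated by penalized least
    squares in the discrete cosine transform domain. Also provides the
    exact order-statistic theory of the minimum L1 distance between
    tested points and the optimum (distance distributions, moments, and
    the focused-refinement decay curve) and a benchmarking harness that
    measures search cost and success rate over repeated seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
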