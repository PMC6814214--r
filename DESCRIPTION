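Package: proptab
Title: Margin-Invariant Proportional Coordinates and Effect Sizes for 2x2
    Contingency Tables
Version: 0.1.0
Authors@R:
    person("proptab", "developers", email = "proptab@example.org",
           role = c("aut", "cre"))
Description: Factors a 2x2 contingency table into diagonal marginal-sum and
    proportion matrices and represents its proportional content as two points
    in the standard one-simplex, reduced to center-of-mass coordinates
    (delta, mu). Classical effect sizes (odds ratio, Yule's Q, relative risk,
    phi, simple matching, Cramer's V, Goodman-Kruskal tau) are exposed as
    perspective functions of these coordinates, making their marginal-sum
    dependence explicit. Includes fixed-margin Monte Carlo confidence
    intervals for any table statistic, a single-node CART association scan
    with a column-sum-invariant delta split criterion, sample-size-adjusted
    logistic curves for imbalanced binary responses, synthetic data
    generators, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
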