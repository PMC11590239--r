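Package: risknet
Title: Risk-Factor Correlation Networks with Centrality and Bootstrap
    Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Psychometric network analysis for questionnaire-based risk-factor
    cohorts: Spearman correlation networks over mixed (numeric, binary,
    ordinal, count) variables, strength, closeness and betweenness centrality
    with descending ranks and percentile ranks, absolute-value threshold
    filtering, Fruchterman-Reingold and circular layouts, non-parametric
    bootstrap of edge weights, and the case-dropping correlation-stability
    (CS) coefficient for centrality indices. Ships a transcribed 34-variable
    Spearman matrix from an adolescent suicide-attempter cohort as a packaged
    fixture and a Gaussian-copula synthetic-cohort generator calibrated to
    that study's marginal distributions, so every analysis stage can be
    exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Matrix,
    jsonlite,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
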