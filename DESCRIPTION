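Package: htavalue
Title: Value Framework Engine for Rapid Health Technology Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multi-criteria value framework for rapid health
    technology assessment (HTA) coverage recommendations. Technologies are
    scored on three ordinal domains (quality of evidence, net clinical
    benefit, economic impact), the triple is mapped through a monotone 4x4x3
    recommendation matrix to a five-level colour-coded coverage
    recommendation, and a documented deliberative adjustment can shift the
    result by at most one level. Includes the economic threshold rules
    (cost-effectiveness versus GDP per capita, budget impact, incremental
    cost, small-population criterion), portfolio analytics that summarise a
    set of assessments into recommendation distributions, combination
    tabulations, cross-tabs and production-timing statistics, figure
    renderers for the portfolio, a packaged reference portfolio, a seeded
    synthetic portfolio generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
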