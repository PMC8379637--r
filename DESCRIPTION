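Package: poolcost
Title: Rate-Cost Analysis of Pooled Testing Strategies for Epidemic
    Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for planning pooled (group) testing of a population when
    tests are scarce and every individual must nevertheless be assigned an
    infection status. Provides closed-form rate (tests per individual) and
    expected misclassification cost for k-stage nested group-testing
    strategies, an information-theoretic lower bound on the cost achievable
    at any test budget (the parametric distortion-rate curve of a Bernoulli
    source under asymmetric false-positive/false-negative costs), a convex
    rate-cost frontier per subpopulation, a greedy optimal allocation of a
    global test budget across heterogeneous subpopulations, and a seedable
    Monte-Carlo simulator that verifies the closed forms. Scenario
    configurations are read from YAML or JSON and a historical
    four-subpopulation scenario ships as a packaged fixture.
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
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
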