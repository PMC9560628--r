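Package: valuedp
Title: Optimal Policies and Simulation for Multi-Alternative Value-Based Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dynamic-programming solutions of the Bellman equation for
    two- and three-alternative value-based decision problems under linear
    (Bayes-Risk) and geometric time costs, with linear or logistic subjective
    utility. Includes a conjugate Gaussian evidence-accumulation model,
    backward induction on a grid of posterior-mean estimates, extraction of
    decision-boundary slices along the equal-value diagonal, a seeded
    stochastic simulator of Bayes-optimal agents producing reaction-time
    summaries and magnitude-sensitivity curves, and generators for
    psychophysics trial schedules and foraging designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
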