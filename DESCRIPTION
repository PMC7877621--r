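Package: vaxpda
Title: Portfolio Decision Analysis for Rapid-Response Vaccine Platform Investments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for portfolio decision analysis of rapid-response vaccine
    platform development projects. Simulates expert-elicited probability-of-success
    (PoS) assessments with triangular three-point distributions, estimates
    platform-type preference weights from a discrete choice experiment via
    conditional logistic regression, combines both into a stochastic portfolio
    value under common random numbers, and solves the chance-constrained binary
    project-selection problem by exact enumeration and by an evolutionary
    algorithm. Includes efficiency-frontier construction, PoS-to-cost ranking
    comparators, mean-variance and mean-Gini stochastic dominance statistics,
    and pairwise rank-probability robustness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    readxl,
    stats,
    survival,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
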