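Package: odorspace
Title: Packing Bounds and Sensitivity Analysis for Olfactory Mixture
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating how many multi-component odor mixtures
    humans can discriminate from three-alternative forced-choice (3-AFC)
    discrimination data.  Implements exact constant-weight-code packing
    bounds (Hamming-type upper bound and Gilbert-Varshamov-type lower
    bound) on the number of mutually discriminable mixtures, exact
    binomial hypothesis testing of discrimination performance against
    chance, difference-limen estimation by linear regression and
    interpolation, and systematic sensitivity analyses of the resulting
    estimate with respect to significance level, sample sizes, thresholds
    and component-library size.  Includes a seeded generator of synthetic
    trial-level 3-AFC datasets with a logistic psychometric link, and
    arbitrary-precision integer combinatorics so that binomial
    coefficients such as choose(128, 30) are handled exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
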