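Package: compsel
Title: Simulating Compensatory Selection Effects in Selective Admissions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo simulator of compensatory selection (collider
    bias, Berkson's paradox) in selective admissions. Generates applicant
    cohorts from latent standard-normal characteristics, maps them to
    observable percentile-ranked predictors (standardized test, grades,
    letters, personal statement) through factor loadings and measurement
    noise, applies weighted-sum or cutoff admissions policies, and
    measures how selection distorts the correlation and regression slope
    between test percentile and binary degree completion. Includes
    ground-truth scenarios (invalid test, valid uncorrelated, valid
    over-weighted, valid correlated predictors), a grid experiment across
    scenarios and policies, and a selectivity sweep from 100% to 5%
    acceptance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
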