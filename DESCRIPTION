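Package: corsurvey
Title: Continuum-of-Resistance Analysis of Survey Non-Response Bias in
    Alcohol Consumption Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the fielding of a general population health survey
    (contact attempts, unit non-response, interview weighting) together with
    person-level alcohol consumption, and analyses the resulting data under
    the continuum of resistance model: weighted descriptive tables by
    contact-attempt group, sex-stratified weighted logistic regression of
    guideline-exceedance outcomes, and non-response-adjusted consumption
    estimates that treat non-participants as exchangeable with the
    hardest-to-contact participants. Includes comparison of survey estimates
    against per-capita alcohol sales.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
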