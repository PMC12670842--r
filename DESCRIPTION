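Package: demlife
Title: Multi-State Life Tables and Years Lived with Dementia from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the individual-level burden of dementia from
    quarterly health-insurance claims panels.  Provides internal validation
    of ICD-10 dementia diagnoses, exact-month person-years computation by
    single year of age, negative binomial period-trend regression, Kannisto
    logistic smoothing of old-age rates, a three-state (illness-death)
    Markov life table yielding decrement-weighted average life expectancy
    with and without dementia, excess life years lost and the
    dementia-to-total ratio, and binomial-bootstrap percentile confidence
    intervals.  A synthetic-claims generator with known ground-truth
    transition hazards makes the full pipeline testable without access to
    restricted claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
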