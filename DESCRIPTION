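Package: vectorcycle
Title: Feeding-Cycle Models and Behavioural Indicators for Malaria Vector Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for measuring, manipulating and exploiting the
    behaviours of adult malaria vector mosquitoes. Implements a closed-form
    absorbing-process model of a single gonotrophic (feeding) cycle over
    behavioural compartments (human indoor in bed / out of bed, human outdoor,
    livestock, other animals), the bed-net-induced multiplication of host
    encounters and the resulting mosquito population coverage of indoor
    residual spraying, sequential layering of vector-control interventions
    with behavioural redistribution of residual blood meals, estimators for
    field-surveyed behavioural indicators (human blood index, indoor/outdoor
    exposure distributions, indoor-resting fraction) with score confidence
    intervals, a threshold rules engine mapping indicator profiles to
    applicable control technologies, and a synthetic entomological survey
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
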