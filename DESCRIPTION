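Package: breechscan
Title: Evaluating Universal Late-Pregnancy Ultrasound Screening for Breech Presentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for before/after evaluation of maternity screening-policy
    changes aimed at reducing undiagnosed breech presentation at term.
    Provides record-level cohort validation, exclusion and aggregation into
    two-epoch outcome summaries; descriptive epoch comparisons; Bayesian
    log-binomial risk-ratio inference with informative priors elicited from
    published effect estimates, fitted by an adaptive random-walk Metropolis
    sampler and validated against a deterministic grid-integration oracle;
    number-needed-to-scan with Wald intervals; interrupted time-series
    analysis of monthly event counts with spline trends; and a seeded
    synthetic cohort generator so the whole pipeline is testable without
    access to hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
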