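Package: nephrospan
Title: Life Expectancy by Kidney Function and Albuminuria Strata
Version: 0.1.0
Authors@R:
    person("nephrospan", "developers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Estimates remaining life expectancy for cohorts stratified by
    kidney function and albuminuria. Computes estimated glomerular filtration
    rate (eGFR) with the 2009 CKD-EPI creatinine equation, categorizes eGFR
    and albuminuria (albumin-to-creatinine ratio or urine dipstick), assigns
    KDIGO 2012 risk classes, splits follow-up into five-year age bands on the
    age time scale with left truncation at 40, and builds Chiang abridged
    life tables with variances and 95% confidence intervals on life
    expectancy and on life-expectancy differences between strata. Includes a
    synthetic-cohort generator with known piecewise-constant stratum hazards
    and a closed-form life-expectancy oracle, so that classification,
    exposure splitting and life-table estimation are testable by parameter
    recovery without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
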