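Package: hospgrowth
Title: Decomposition of Hospital Activity Growth into Demographic,
    Health-Status and Residual Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes annual growth in hospital activity (elective,
    non-elective and maternity admissions, outpatient and emergency
    department attendances) into multiplicative components attributable to
    population size (P), age-sex structure (S), age-specific health status
    (H) and residual factors (R), so that total growth satisfies
    G = (1+P)(1+S)(1+H)(1+R) - 1.  Components are estimated from a ladder of
    nested negative-binomial spline regressions with population offsets;
    the health-status component uses a "health-status age" covariate built
    from Sullivan-method disability-free life expectancy.  Includes Wald
    intervals for G and R, Monte-Carlo intervals for the coefficient-ratio
    components P, S and H, a synthetic-data generator with known ground
    truth for end-to-end validation, and record-level ingest filters for
    event data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    MASS,
    splines,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
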