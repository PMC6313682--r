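Package: pmexposure
Title: Microenvironmental Time-Activity Modelling of Daily PM2.5 Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates daily personal exposure to fine particulate matter
    (PM2.5) from microenvironmental concentration measurements and 10-minute
    time-activity diaries. Builds a 144-slot by 3-microenvironment diurnal
    concentration grid from 1-minute measurements (with gravimetric
    correction and per-cell distribution fitting), computes deterministic
    time-weighted daily exposures, simulates population exposure
    distributions by Monte-Carlo draws from the fitted per-slot
    distributions, and characterizes the top-5 percent exposure group with
    exact tests, collinearity screening and multivariate logistic
    regression. Includes synthetic measurement-campaign and diary-population
    generators so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
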