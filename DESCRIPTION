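Package: qalythreshold
Title: Supply-Side Cost-Effectiveness Thresholds from Hospital Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the opportunity cost of hospital care (a supply-side
    cost-effectiveness threshold, in euro per quality-adjusted life year) from
    patient-group panel data. Builds group-level QALY-loss outcomes from EQ-5D
    questionnaire records and mortality counts (discounted healthy life
    expectancy, burden-of-disease correction), removes last-year-of-life costs
    from raw spending to break reverse causality, fits a fixed-effects translog
    production function, and derives the elasticity of spending at the sample
    mean and the marginal cost per QALY with cluster-bootstrap and Monte Carlo
    uncertainty. Includes a seeded synthetic-data generator emulating the
    gender x age-band x disease-group panel structure of Dutch hospital claims
    so the full pipeline is testable without confidential microdata.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
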