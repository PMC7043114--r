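Package: p2i
Title: Deterministic Portfolio-to-Impact Modelling of Vaccine Development Pipelines
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic product-development portfolio model for vaccine
    pipelines. Candidates are classified into archetypes carrying per-phase
    cost, duration and probability-of-success assumptions; the model derives
    risk-adjusted development costs, calendar-year cost accrual, launch
    probabilities and launch timing over a fixed horizon, and supports
    parameter-override scenarios and multiplicative sensitivity analysis.
    Ships the 18-candidate European Vaccine Initiative portfolio and the
    published archetype parameter set as fixtures, plus a seeded generator of
    structurally similar synthetic portfolios for property testing.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
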