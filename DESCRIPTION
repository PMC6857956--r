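Package: smartbp
Title: Smart-Schedule Blood Pressure Telemonitoring: Protocol Engine,
    Cohort Simulator and Study Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a remote blood-pressure monitoring protocol for
    hypertensive patients reporting home readings by SMS text message or
    automated phone call: parsing and validation of free-text readings,
    per-patient baseline computation, a dynamic ("smart") prompt schedule
    that switches between daily and thrice-weekly messaging based on
    two-week mean blood pressure, one-time and biweekly-mean alert rules,
    and triaged provider reports. Ships a seeded synthetic-cohort
    simulator with configurable adherence, measurement noise and
    programmed blood-pressure decline, and an analysis pipeline for the
    usual feasibility-study statistics: response rates, risk
    stratification at 140 mm Hg systolic, paired and unpaired t
    comparisons, Fisher's exact test with cross-product odds ratios,
    biweekly proportion series, cohort flow counts and satisfaction
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
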