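Package: herdsync
Title: Reproductive and Economic Evaluation of Pre-Breeding Synchronization in Seasonal Dairy Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to compare a single-prostaglandin pre-breeding treatment
    (PGOD) against a modified Ovsynch fixed-time AI protocol (MOFT) in
    seasonal (autumn-calving) dairy herds. Provides a seeded cow-level
    breeding-season simulator with right-censored conception outcomes, a
    first-principles Kaplan-Meier/Greenwood/log-rank survival toolkit with
    herd fertility summaries (submission rate, interval in-calf rates,
    services per conception, barren rate), a Schoenfeld sample-size
    calculation, and a partial-budget economic model of the protocol switch
    with one-way (tornado) sensitivity analysis and triangular-distribution
    Monte-Carlo uncertainty propagation across four dry-off by barren-rate
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
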