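Package: pbrm
Title: Performance-Based Reimbursement for Multi-Centre Clinical Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An activity-based ("performance-based") reimbursement engine for
    multi-centre clinical cohort studies. Models a cost catalogue of
    reimbursement items (role time at tariff rates plus materials and
    overheads), reads pseudonymised exports of the three study data-management
    systems (clinical documentation, biosampling, imaging uploads), links them
    into reimbursement cases via a trusted-third-party style pseudonym table,
    applies eligibility and quality gates, and produces itemised, audited case
    statements with centre and cohort aggregation. Includes formal comparison
    of the performance-based model against fixed-rate and up-front allocation
    funding models (with quarter-FTE rounding and target-number capping), a
    cases-per-budget-unit cost-efficiency statistic with one-way ANOVA, and a
    seeded synthetic multi-centre cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
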