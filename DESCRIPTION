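Package: funnelbench
Title: Continuous Scientific Benchmarking Harness with Energy-Funnel
    Quality Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale continuous benchmarking harness for stochastic
    molecular-modelling protocols. Provides Boltzmann-weighted funnel-quality
    scoring (P_Near) of score-vs-rmsd decoy ensembles, correlation and
    sequence-recovery metrics, winner-takes-all and column-average
    aggregation across score functions, a strict test-directory contract
    with numbered stage execution and cutoff-based pass/fail including a
    stochastic-failure rerun policy, rolling revision scheduling with
    automatic bisection to the breaking revision, a mock Monte-Carlo
    protocol simulator for end-to-end testing, and static HTML dashboards
    and per-run results pages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
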