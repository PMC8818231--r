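Package: wrecs
Title: Weighted Composite Time-to-Event Endpoints with Recurrent Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of weighted composite time-to-event endpoints that
    combine a recurrent non-fatal event with a fatal event in two-arm
    clinical trials.  Implements three relevance-weighted approaches: the
    Wei-Lachin weighted hazard ratio built on stratified cause-specific
    Cox models with a cross-cause sandwich covariance, the weighted
    all-cause hazard ratio with a stratified weight-based log-rank test
    and bootstrap confidence intervals, and the Bakal weighted
    Kaplan-Meier estimate with a modified log-rank test.  Includes a
    parametric recurrent-event simulation engine (constant, linear and
    power hazards with administrative censoring) and a scenario runner
    for Monte-Carlo power and estimator studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
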