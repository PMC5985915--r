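Package: staterank
Title: Monte Carlo Rank Uncertainty for State-Level Survey Prevalence Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ranks geographic units (states) on survey-estimated behavior
    prevalence with honest uncertainty. Simulates joint rank distributions by
    Monte Carlo, reports median ranks with 95 percent rank confidence
    intervals (individual percentile or simultaneous), estimates design-based
    prevalence and Taylor-series-linearization standard errors from weighted
    stratified-cluster microdata, and quantifies rank consistency across
    surveys and behaviors with tie-corrected Spearman correlations and paired
    t tests with Bonferroni adjustment. Ships state-level adolescent
    substance-use prevalence tables from two national surveillance surveys as
    packaged fixtures, and a synthetic-data generator with known ground truth
    for coverage and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
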