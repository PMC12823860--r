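Package: strokeCUA
Title: Cost-Utility Modelling of Extended-Window Thrombolysis in Posterior Circulation Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A hybrid decision-tree and Markov cohort model for cost-utility
    analysis of intravenous alteplase versus standard medical therapy in
    posterior circulation ischemic stroke treated 4.5-24 hours after onset.
    Implements a 3-month decision tree feeding a 119-cycle Markov model over
    modified Rankin Scale (mRS) health states with age-dependent background
    mortality, recurrent stroke, half-cycle correction and discounting;
    incremental cost-effectiveness ratios and net monetary benefit against
    GDP-based willingness-to-pay thresholds; one-way (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves; a microsimulation validation oracle; and a synthetic two-arm
    trial generator for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
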