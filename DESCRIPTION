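Package: fnirstransfer
Title: Transfer Learning for fNIRS Mental-Workload Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for subject-transfer learning in
    functional near-infrared spectroscopy (fNIRS) brain-computer interfaces.
    Generates synthetic multi-subject n-back cohorts with a forward optical
    model (modified Beer-Lambert law), converts optical density to hemoglobin
    concentration changes, low-pass filters and epochs the signals, trains a
    compact convolutional neural network, and compares a pretrain/freeze/
    fine-tune protocol against training from scratch across epoch budgets,
    including the Shapiro-Wilk / paired t-test statistical comparison of the
    resulting subject-by-budget accuracy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
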