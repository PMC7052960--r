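Package: imgcea
Title: Cost-Effectiveness Analysis of Diagnostic Imaging Strategies via
    Decision Tree and Markov Cohort Modelling
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines a diagnostic decision tree with a five-state Markov
    cohort model of recurrent prostate cancer to compare imaging strategies
    for bone-metastasis detection on cost and quality-adjusted life-years.
    Includes life-table utilities with age-dependent background mortality,
    diagnostic accuracy statistics with paired-test comparisons (Cochran Q,
    McNemar, Cohen's kappa), efficiency-frontier and ICER computation with
    strict and extended dominance, one-way deterministic and probabilistic
    (Monte Carlo) sensitivity analyses with acceptability curves, and a
    synthetic-data layer (trial generator, gamma cost logs, Gompertz life
    tables) so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
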