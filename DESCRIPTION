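Package: netlesion
Title: Lesion Simulation and Strain-Based Concussion Prediction on
    Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: In-silico lesioning of weighted structural brain networks and
    strain-based concussion risk modeling. Computes weighted global and
    local efficiency, performs exhaustive single-, pair- and triple-node
    deletion sweeps with rank-aggregated region importance scores, ranks
    regions by finite-element-derived maximum principal strain, tests
    regional strain differences between concussive and non-concussive
    impacts (Wilcoxon rank-sum with Bonferroni correction), and evaluates
    logistic-regression concussion prediction under leave-one-out
    cross-validation with accuracy, sensitivity, specificity and AUC.
    Includes a seeded synthetic-data generator producing parcellations,
    connectome cohorts with planted hubs, and impact datasets with planted
    high-strain regions, plus an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
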