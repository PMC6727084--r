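Package: aftfuse
Title: Integrative Penalized Accelerated Failure Time Models Across Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Marginal (per-gene) and joint (all-gene) accelerated failure time
    models fitted jointly across multiple cancer cohorts. The loss is
    Kaplan-Meier (Stute) weighted least squares on log survival times; sparsity
    is imposed with the minimax concave penalty (MCP), and similarity of gene
    effects across cohorts is promoted with magnitude-based or sign-based
    fusion penalties. Includes coordinate-descent solvers, cross-validation and
    BIC tuning, evaluation metrics (relative overlap, relative Euclidean
    distance, concordance statistics, selection TPR/FPR), and a simulation
    study generator with calibrated exponential censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
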