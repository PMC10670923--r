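Package: trajqtl
Title: Functional Mapping of Longitudinal Growth Traits in Clonal Tree Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits four sigmoidal growth laws (Gompertz, Chapman-Richards,
    logistic, asymptotic regression) to multi-year height and diameter
    records from clonal field trials, selects the best law by paired
    significance comparison of five fit metrics (AIC, BIC, R2, RMSE, MAE),
    tests SNP genotype effects on whole growth trajectories with a
    likelihood-ratio statistic against a chi-square reference, stages
    ontogeny by points of maximum curvature into rapid and reduced growth
    phases, and runs per-year single-marker association and multivariate
    association of fitted curve parameters. Includes a seeded synthetic-data
    generator emulating a 24-clone poplar trial with an irregular
    measurement schedule, and an end-to-end pipeline with CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
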