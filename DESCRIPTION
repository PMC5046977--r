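Package: epitoc
Title: Epigenetic Mitotic Clock Construction, Scoring and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for building and applying DNA-methylation mitotic
    clocks. Constructs clock CpG sets from a methylation cohort by a
    covariate-adjusted age EWAS with FDR control followed by promoter,
    fetal ground-state and Polycomb-target filters; computes
    hyper/hypomethylation clock scores (pcgtAge/hypoAge) as mean beta
    values over the clock CpGs; calibrates score against age per tissue
    and inverts the calibration to estimates of cumulative stem-cell
    divisions (TNSC) given literature division rates; computes a
    nine-gene expression-based mitotic index; provides the validation
    statistics (age-adjusted association, one-tailed rank tests, ROC/AUC
    with DeLong or bootstrap confidence intervals, age matching, binomial
    comparison of significance counts); and includes a generative
    simulator of the replication-error model with cell-type-mixture
    confounding so every step is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    quadprog,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, MethylationArray, StatisticalMethod
RoxygenNote: 7.3.3
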