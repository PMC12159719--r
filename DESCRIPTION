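Package: metEnsembleGP
Title: Environment-Ensemble Genomic Prediction for Multi-Environment Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction from sparse multi-environment trial (MET)
    phenotype and SNP data. Computes per-location genotype BLUEs and
    broad-sense heritability from year-adjusted mixed models, trains
    singular, environment-ensemble and optimized-ensemble predictors over
    ordinary least squares, ridge regression and feed-forward neural
    network base learners, evaluates them by leave-one-location-out
    cross-validation with Pearson-correlation accuracy, and characterizes
    test environments through GGE biplot geometry (environment-centered
    SVD, vector lengths and angles). A synthetic MET generator with a
    known-truth channel emulates the statistical structure of a sparse
    cooperative nursery trial so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
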