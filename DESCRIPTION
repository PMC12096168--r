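Package: healthequity
Title: Influencing-Factor and Equity Analysis of Health-Service Utilization in Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing utilization of a binary health
    service (such as health education) in categorical survey microdata on
    migrant populations: Pearson chi-square screening of candidate factors,
    out-of-bag permutation importance from a bagged decision-tree ensemble
    with randomized hyperparameter search, L1-penalized logistic variable
    selection with cross-validation, binary logistic modelling with odds
    ratios and average marginal effects, and income-rank equity analysis via
    the concentration index, concentration curve and Wagstaff decomposition.
    Includes a synthetic microdata generator with known generative
    parameters so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
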