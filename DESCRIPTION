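Package: emmayield
Title: Perturbation-Theory Moving-Average Models of Ruminant Growth Yield
    from Gastrointestinal Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds Expected Measurement Moving Average (EMMA) machine-learning
    models that predict ruminant growth yield from the spatiotemporal mRNA
    expression of Ghrelin and growth hormone receptor (GHR) along the
    gastrointestinal tract. Provides qPCR 2^-ddCt relative-expression and
    carcass-yield derivation, stage summaries and orthogonal age contrasts,
    Box-Jenkins moving-average operators over experimental-condition classes,
    pairwise query/reference perturbation-case construction, min-max
    normalization, residual-based outlier filtering, and a seeded regression
    suite (OLS with full inference, stepwise selection, PLS, Lasso, Elastic
    Net, neural networks, random forests) with evaluation, permutation
    importance, and Bonferroni-corrected pairwise model comparison. A
    synthetic-study generator with planted ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mixOmics,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
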