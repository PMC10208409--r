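Package: TMBserval
Title: Multiple-Instance Calibration Learning for Multidimensional Tumor
    Mutation Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps multidimensional tumor mutation burden (TMB) vectors to
    subgroup-level immunotherapy prognosis labels with a multiple-instance
    regression network trained under statistically interpretable losses.
    Burden vectors are counted per mutation class (SNV, insertion, deletion)
    from filtered variant calls; patient subgroups ("bags") carry either
    expert category labels or objective probabilistic labels combining the
    objective response rate with Cox proportional-hazards survival
    probabilities.  Training minimises either a Hosmer-Lemeshow-style
    calibration loss or a vector distance loss (squared Euclidean,
    Mahalanobis, Minkowski) by full-batch gradient descent.  Includes
    k-fold cross-validation, learning curves, Hosmer-Lemeshow
    goodness-of-fit evaluation, baseline-learner comparison, and a
    synthetic survival-cohort simulator with calibrated subgroup labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    survival,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
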