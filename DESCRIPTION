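Package: lifecourseMR
Title: Lifecourse Mendelian Randomisation with Recall-Anchored Childhood BMI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates the direct causal effects of childhood and adulthood
    body-mass index on type-2-diabetes-related traits using two-sample
    Mendelian randomisation. Provides a continuous reconstruction of
    childhood BMI from three-level recall categories anchored to an external
    reference distribution, rank-based inverse-normal transformation,
    vectorised covariate-adjusted GWAS, quality-control filtering and greedy
    LD clumping to define independent instruments, genetic-risk-score
    validation metrics (variance explained, regression R-squared,
    extreme-value prediction, instrument F-statistics), and an MR engine with
    inverse-variance-weighted, MR-Egger and multivariable estimators, Steiger
    directionality filtering, proxy-variant lookup, allele harmonisation and
    fixed-effect meta-analysis. A cohort simulator generates two-sample
    studies under the assumed causal diagram (child-to-adult path, direct
    effects, hidden confounding, optional directional pleiotropy) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    vcfR,
    metafor
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
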