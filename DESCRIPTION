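Package: metaRT
Title: Response-Time-Based Type-2 ROC and Meta-d' Analysis for 2AFC Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how well a secondary variable (confidence,
    response time, or a logistic confidence-RT composite) discriminates an
    observer's own correct and incorrect responses in two-alternative
    forced-choice tasks. Implements quantile binning of response times,
    type-2 ROC curves and AUC, maximum-likelihood meta-d' estimation
    (Maniscalco-Lau), per-subject logistic confidence-RT composites,
    split-half reliability with Spearman-Brown correction and disattenuated
    correlations, random-effects meta-analysis of cross-subject correlations,
    and a two-stage dynamic signal detection (2DSD) simulator (drift
    diffusion with post-decisional evidence accumulation) that generates
    realistic trial-level behaviour for testing every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
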