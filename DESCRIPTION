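Package: gradmap
Title: Functional Connectivity Gradients from Parcellated Resting-State Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cortical functional-connectivity gradients from parcellated
    resting-state fMRI time series: Fisher-z connectivity matrices, row-sparsified
    cosine affinity kernels, diffusion-map embeddings, group templates with
    orthogonal Procrustes alignment, and network-level gradient metrics
    (within-network scores, within- and between-network dispersion, global
    gradient variation). Includes covariate-adjusted group statistics (Hotelling's
    T-squared and univariate linear models with Bonferroni correction), Spearman
    correlation screens with Fisher-transform confidence intervals, a boosted-tree
    nested cross-validation framework for predicting cognitive scores from
    network gradient features, and a synthetic-cohort generator with planted
    group effects for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
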