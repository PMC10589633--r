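Package: rarecascade
Title: Multi-Omics Outlier Detection and Rare-Variant Prioritization Across
    the Regulatory Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects molecular outliers in longitudinal multi-omics cohorts
    (gene expression, DNA methylation, splicing, plasma protein abundance)
    and prioritizes the rare genetic variants that drive them. Provides
    residual Z-score outlier calling across two exams, a Dirichlet-Multinomial
    splicing-outlier statistic with Mahalanobis-distance empirical p-values,
    rare-variant enrichment statistics (relative risk with confidence
    intervals and enrichment comparison tests), and the multi-omics Watershed
    model: a conditional-random-field latent-variable model linking genomic
    annotations to latent regulatory states and observed outlier statuses,
    trained by expectation-maximization with exact inference over the latent
    states and evaluated on held-out pairs of individuals sharing identical
    rare variants. A cohort simulator with known generating parameters
    supports testing every component without access to restricted data.
    Downstream utilities connect variant posteriors to complex traits via
    percentile-normalized effect-size comparisons and gene-level association
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
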