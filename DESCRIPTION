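Package: twinherit
Title: Twin-Based Heritability Analysis of Gene Expression
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for classical-twin heritability analysis of
    expression microarray data. Per-probe additive-genetic (A), shared-
    environment (C) and unique-environment (E) variance components are
    estimated by maximum likelihood from monozygotic and dizygotic twin
    pairs, with model selection across ACE/AE/CE/E by likelihood ratio and
    AIC, heritability p-values from the AE-vs-E comparison, Benjamini-
    Hochberg false discovery rate control, profile-likelihood and bootstrap
    confidence intervals, gene-level aggregation by the maximum-probe rule,
    Fisher's exact gene-list enrichment, heritability-vs-gene-feature
    correlations, and cross-cohort harmonization of per-gene heritability
    summaries by Ensembl id. A seeded synthetic twin-expression generator
    with known ground truth makes the whole pipeline exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
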