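Package: mirnetmeta
Title: Meta-Analysis and Regulatory-Network Integration for microRNA
    Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for evaluating a candidate microRNA
    across expression cohorts and downstream gene-level evidence. Provides
    two-group comparisons from summary statistics (Welch and pooled t,
    fold-change screening, diagnostic ROC), standardized-mean-difference
    random-effects meta-analysis with heterogeneity and publication-bias
    diagnostics, hypergeometric literature co-citation scoring with
    alias-based gene-symbol normalization, consensus target-prediction
    voting across platforms, gene-set integration and pathway enrichment,
    hub-gene connectivity testing, and multi-source regulatory-network
    assembly with SIF/GraphML export. Seeded synthetic-data generators
    emulate every input so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pROC,
    igraph,
    jsonlite,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
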