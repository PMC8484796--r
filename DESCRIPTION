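Package: m6ascape
Title: m6A-Regulator Modification Patterns, Scoring, and Survival Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of expression-defined m6A (N6-methyladenosine) regulator
    modification patterns in tumor cohorts by resampling consensus clustering,
    single-sample gene-set enrichment scoring of immune and pathway activity,
    derivation of a per-sample m6A score signature (moderated-t differential
    expression, random-forest redundancy removal, univariate Cox filtering,
    sign partition and scale(sum(X) - sum(Y)) scoring with median split), and
    the downstream survival, mutation-frequency and association statistics.
    Multi-cohort matrices are merged with empirical-Bayes location/scale batch
    adjustment. A fully deterministic synthetic-cohort generator provides
    planted clusters, batch effects, proportional-hazards survival and
    mutation frequencies so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    limma,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    pROC,
    mclust,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
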