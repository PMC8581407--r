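Package: inflaclust
Title: Inflammasome-Signaling Scoring, Consensus Subtyping and Subtype
    Prediction for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inflammasome signaling in bulk tumor
    transcriptomes and to derive and predict inflammasome-based molecular
    subtypes. Implements directional gene-set curation (differential
    expression screens and consistent-direction meta-analysis votes),
    single-sample GSEA (ssGSEA) enrichment scoring with
    positive-minus-negative composite scores for the CASP1, GSDMD, IL1B and
    IL18 signaling nodes, resampled K-means consensus clustering with
    delta-area and silhouette diagnostics for cluster-number selection,
    semantic cluster labeling, cluster characterization (hypergeometric
    tumor-type enrichment, one-vs-rest differential feature screens,
    Euclidean tumor-map similarity, log-rank and pairwise Cox survival
    contrasts), a six-algorithm validation harness with an SVM subtype
    predictor for external cohorts, and a seeded synthetic-cohort generator
    with planted cluster structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    yaml,
    survival,
    e1071,
    MASS,
    nnet,
    rpart,
    class,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster
Config/testthat/edition: 3
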