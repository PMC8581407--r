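# inflaclust

Inflammasome-signaling scoring, consensus subtyping and subtype prediction
for tumor transcriptomes.

Inflammasomes — cytoplasmic sensors such as NLRP3 and AIM2 — activate
caspase-1, which cleaves GSDMD, IL-1B and IL-18 and drives pyroptotic,
inflammatory cell death. How far this cascade runs varies widely across
tumors and shapes their immune microenvironment. `inflaclust` turns a bulk
gene-by-sample expression matrix into a per-sample readout of the cascade
and derives reproducible inflammasome subtypes from it. It is aimed at
computational oncologists working with pan-cancer or single-disease RNA-seq
cohorts.

## The method in brief

Five directional gene sets cover the cascade's three steps: sensing (the
15 inflammasome-complex "IC" genes), activation (CASP1-regulated genes) and
termination (GSDMD-, IL1B- and IL18-regulated genes). Each sample gets five
scores. The IC score is the ssGSEA enrichment of the core set,

```
ES = sum_j [ cum. in-set weight fraction(j) - cum. out-of-set count fraction(j) ],
w_i = rank_i^alpha  (alpha = 0.25),
```

summed over the sample's descending expression ranking. The four regulated
nodes undergo post-translational control, so their activity is read out
indirectly as a directional composite:

```
score(X) = ES(X_up) - ES(X_dn),    X in {CASP1, GSDMD, IL1B, IL18}.
```

The samples x 5 matrix (z-scored per column) is clustered by resampled
K-means consensus clustering (Euclidean; consensus entry = co-clustering
frequency among co-sampled pairs). The cluster number is selected from the
consensus-CDF delta area and average silhouette width, the six clusters are
named by their centroid pattern (`IC^Low IL1B^Low` ... `IC^High IL18^High`),
and the subtypes are characterized by hypergeometric tumor-type enrichment,
one-vs-rest feature screens, tumor-map similarity `S = 1/(1 + d)` and
log-rank / pairwise Cox survival contrasts. A six-algorithm validation
harness (CART, LR, LDA, KNN, NB, SVM; stratified 80/20 split with five-fold
CV) backs an RBF-SVM predictor that assigns subtypes to external cohorts
while re-applying — never refitting — the training standardization.

A seeded synthetic-cohort generator plants the six score patterns, uneven
tumor-type compositions and cluster-dependent exponential survival, so the
whole pipeline is testable end-to-end without consortium data. The packaged
gene sets are a synthetic structural stand-in (141 unique genes: 15 IC, 34
CASP1, 13 GSDMD, 72 IL1B, 8 IL18); load a curated compendium with
`load_scheme()` for scientific use. See `vignettes/inflammasome-subtyping.Rmd`
for assumptions, parameter rationale and limitations.

## Worked example

```r
library(inflaclust)

cohort <- generate_cohort(synthetic_config(seed = 1, samples_per_cluster = rep(50L, 6)))
scores <- score_matrix(cohort$expr, default_scheme())   # 300 samples x 5 scores
cc     <- consensus_cluster(scores, k_range = 2:8, resamples = 100, seed = 1)
print(cc)
#> consensus_result over K = 2, 3, 4, 5, 6, 7, 8
#>   K   cdf_area  delta_area  silhouette
#>   2   0.305     0.305       0.412
#>   3   0.615     1.016       0.448
#>   4   0.725     0.178       0.524
#>   5   0.783     0.080       0.544
#>   6   0.836     0.068       0.566
#>   7   0.847     0.013       0.550
#>   8   0.860     0.015       0.509
```

The delta area collapses after K = 6 (0.068 to 0.013) while the silhouette
peaks there (0.566): `select_k(cc)` returns 6. Labeling the clusters by
their centroids recovers the six canonical names:

```r
labeling <- label_clusters(scores, consensus_labels(cc, select_k(cc)))
labeling[, c("cluster", "semantic", "IC", "IL18")]
#>   cluster          semantic          IC       IL18
#> 1       1   IC^Low IL1B^Low -1.39       -0.55
#> 2       2  IC^Low IL1B^High -1.05        0.13
#> 3       3 IC^Mid CASP1^High  0.02       -0.54
#> 4       4  IC^Mid IL18^High  0.10        1.18
#> 5       5  IC^High IL18^Low  1.15       -1.36
#> 6       6 IC^High IL18^High  1.16        1.14
```

(IC rises from the Low to the High strata; the in-stratum partner score —
IL1B, CASP1-vs-IL18 dominance, IL18 — separates each pair.) The validation
harness and survival contrasts on the same cohort:

```r
two_layer_validate(scores, attr(labeling, "sample_labels"), seed = 1)
#>  algorithm cv_accuracy holdout_accuracy
#>       CART      1.0000                1
#>         LR      0.9958                1
#>        LDA      1.0000                1
#>        KNN      1.0000                1
#>         NB      1.0000                1
#>        SVM      1.0000                1

surv <- survival_contrasts(attr(labeling, "sample_labels"),
                           cohort$survival$time, cohort$survival$event)
surv$logrank
#> chisq 28.35, df 5, p 3.1e-05
subset(surv$pairwise, row_cluster == 6 & col_cluster == 1)$hr
#> [1] 2.24
```

All six classifiers separate this cohort perfectly on the holdout split,
the subtypes differ in survival, and the planted high-hazard
`IC^High IL18^High` cluster shows a hazard ratio of 2.24 against cluster 1.

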