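# shared fixtures built in code; heavier objects are memoised per test run

# tiny hand-sized scheme: every score gets small sets over a 12-gene universe
tiny_scheme <- function() {
  signature_scheme(list(
    IC = list(positive = gene_set("IC_CORE", "sensing", c("g1", "g2", "g3"), "core")),
    CASP1 = list(positive = gene_set("CASP1_UP", "activation", c("g4", "g5"), "up_regulated"),
                 negative = gene_set("CASP1_DN", "activation", c("g6"), "down_regulated")),
    GSDMD = list(positive = gene_set("GSDMD_UP", "termination", c("g7"), "up_regulated"),
                 negative = gene_set("GSDMD_DN", "termination", c("g8"), "down_regulated")),
    IL1B = list(positive = gene_set("IL1B_UP", "termination", c("g9", "g10"), "up_regulated"),
                negative = gene_set("IL1B_DN", "termination", c("g11"), "down_regulated")),
    IL18 = list(positive = gene_set("IL18_UP", "termination", c("g12"), "up_regulated"))
  ))
}

# small random expression matrix
rand_expr <- function(n_genes = 20, n_samples = 6, seed = 1, prefix = "g") {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
              dimnames = list(paste0(prefix, seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  expression_matrix(v)
}

# default synthetic cohort + its standardized score matrix, computed once
.cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.cache$cohort)) .cache$cohort <- generate_cohort(synthetic_config(seed = 1))
  .cache$cohort
}
default_scores <- function() {
  if (is.null(.cache$scores)) {
    .cache$scores <- score_matrix(default_cohort()$expr, default_scheme())
  }
  .cache$scores
}
default_consensus <- function() {
  if (is.null(.cache$cc)) {
    .cache$cc <- consensus_cluster(default_scores(), k_range = 2:8,
                                   resamples = 200, seed = 11)
  }
  .cache$cc
}

# independent literal ssGSEA oracle: walks the ranked list gene by gene
ssgsea_oracle <- function(x, members, alpha) {
  rk <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  genes <- names(x)[ord]
  in_set <- genes %in% members
  n_out <- sum(!in_set)
  w_total <- sum(rk[ord][in_set]^alpha)
  es <- 0; cin <- 0; cout <- 0
  for (i in seq_along(genes)) {
    if (in_set[i]) cin <- cin + rk[ord][i]^alpha else cout <- cout + 1
    es <- es + (cin / w_total - cout / n_out)
  }
  unname(es)
}

# adjusted Rand index (mclust) used as the recovery metric
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
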