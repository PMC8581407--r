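#' Hypergeometric tumor-type enrichment of clusters
#'
#' For every (tumor type, cluster) pair, tests whether the type is
#' over-represented in the cluster: with N samples overall, Kt of the type,
#' n in the cluster and k in the overlap, the p-value is the hypergeometric
#' upper tail `P(X >= k)`. Benjamini-Hochberg adjustment is applied across
#' all pairs.
#'
#' @param cluster_labels Cluster assignment per sample.
#' @param tumor_types Tumor-type label per sample (same order).
#' @return A data.frame with columns `tumor_type`, `cluster`, `n_total`,
#'   `n_type`, `n_cluster`, `overlap`, `p`, `fdr`.
#' @export
hypergeom_enrichment <- function(cluster_labels, tumor_types) {
  if (length(cluster_labels) != length(tumor_types)) {
    fail("cluster labels and tumor types must align on samples")
  }
  N <- length(cluster_labels)
  types <- sort(unique(as.character(tumor_types)))
  clusters <- sort(unique(cluster_labels))
  if (length(types) == 1L) {
    warning("single tumor type: all enrichment p-values are 1", call. = FALSE)
  }
  grid <- expand.grid(tumor_type = types, cluster = clusters,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    tt <- grid$tumor_type[i]; cl <- grid$cluster[i]
    Kt <- sum(tumor_types == tt)
    n <- sum(cluster_labels == cl)
    k <- sum(tumor_types == tt & cluster_labels == cl)
    data.frame(tumor_type = tt, cluster = cl, n_total = N, n_type = Kt,
               n_cluster = n, overlap = k,
               p = stats::phyper(k - 1, Kt, N - Kt, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' One-vs-rest chi-square screen of binary genomic features
#'
#' For each binary feature (e.g. non-silent mutation of a driver gene,
#' presence of a copy-number alteration) and each cluster, tests the 2x2
#' table of feature presence inside vs outside the cluster with a Pearson
#' chi-square statistic (no continuity correction, so the statistic equals
#' the textbook 2x2 form). When any expected cell count falls below 5 the
#' record is flagged and Fisher's exact test supplies the p-value instead.
#' The effect is the in-cluster minus out-of-cluster presence frequency.
#' Constant feature columns are skipped with a notice. BH adjustment is one
#' family across all (feature, cluster) records.
#'
#' @param cluster_labels Cluster assignment per sample.
#' @param features Samples x features binary (0/1) matrix.
#' @param feature_class Label recorded on the output (default
#'   `"binary_genomic"`).
#' @return A data.frame with columns `feature`, `feature_class`, `cluster`,
#'   `effect`, `statistic`, `p`, `fdr`, `exact` (whether the Fisher fallback
#'   was used).
#' @export
chisq_feature_screen <- function(cluster_labels, features,
                                 feature_class = "binary_genomic") {
  features <- as.matrix(features)
  if (nrow(features) != length(cluster_labels)) {
    fail("features must have one row per sample")
  }
  if (!all(features %in% c(0, 1))) fail("features must be binary 0/1")
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("F", seq_len(ncol(features)))
  }
  clusters <- sort(unique(cluster_labels))
  rows <- list()
  for (f in colnames(features)) {
    x <- features[, f]
    if (length(unique(x)) == 1L) {
      message(sprintf("feature '%s' is constant; skipped", f))
      next
    }
    for (cl in clusters) {
      inside <- cluster_labels == cl
      tab <- rbind(c(sum(x[inside] == 1), sum(x[inside] == 0)),
                   c(sum(x[!inside] == 1), sum(x[!inside] == 0)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      exact <- any(expected < 5)
      if (exact) {
        p <- stats::fisher.test(tab)$p.value
        statistic <- NA_real_
      } else {
        ct <- stats::chisq.test(tab, correct = FALSE)
        p <- ct$p.value
        statistic <- unname(ct$statistic)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, feature_class = feature_class, cluster = cl,
        effect = mean(x[inside]) - mean(x[!inside]),
        statistic = statistic, p = p, exact = exact,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) fail("no testable feature columns")
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res[, c("feature", "feature_class", "cluster", "effect", "statistic",
          "p", "fdr", "exact")]
}

# per-class significance thresholds for differential expression calls
DE_THRESHOLDS <- list(
  coding = list(logfc = 1, fdr = 0.01),
  lncRNA = list(logfc = 2, fdr = 0.01),
  miRNA  = list(logfc = 1, fdr = 0.01)
)

#' One-vs-rest differential expression screen
#'
#' For each gene and each cluster, compares the cluster's samples against all
#' remaining samples: the effect is the difference of log-scale means
#' (logFC) and the p-value comes from a two-sample Wilcoxon rank-sum test
#' (normal approximation). BH adjustment forms one family per feature class
#' across all clusters and genes. Significance is called with class-specific
#' thresholds: coding and miRNA need `|logFC| > 1` and `FDR < 0.01`, lncRNA
#' needs `|logFC| > 2` and `FDR < 0.01`. Constant genes get `p = 1` and
#' `logFC = 0`.
#'
#' @param expr An [expression_matrix()].
#' @param cluster_labels Cluster assignment per sample (matrix column order).
#' @param feature_class `"coding"`, `"lncRNA"` or `"miRNA"`.
#' @return A data.frame with columns `feature`, `feature_class`, `cluster`,
#'   `effect` (logFC), `p`, `fdr`, `significant`.
#' @export
diff_expression_one_vs_rest <- function(expr, cluster_labels,
                                        feature_class = c("coding", "lncRNA",
                                                          "miRNA")) {
  stopifnot(inherits(expr, "expression_matrix"))
  feature_class <- match.arg(feature_class)
  v <- expr$values
  if (ncol(v) != length(cluster_labels)) {
    fail("one cluster label per sample required")
  }
  clusters <- sort(unique(cluster_labels))
  counts <- table(cluster_labels)
  if (any(counts < 3) || any(length(cluster_labels) - counts < 3)) {
    fail("each one-vs-rest split needs >= 3 samples per side")
  }
  rows <- lapply(clusters, function(cl) {
    inside <- cluster_labels == cl
    logfc <- rowMeans(v[, inside, drop = FALSE]) -
      rowMeans(v[, !inside, drop = FALSE])
    p <- vapply(seq_len(nrow(v)), function(g) {
      x <- v[g, inside]; y <- v[g, !inside]
      if (max(v[g, ]) == min(v[g, ])) return(1)
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    }, numeric(1))
    constant <- apply(v, 1, function(r) max(r) == min(r))
    logfc[constant] <- 0
    data.frame(feature = rownames(v), feature_class = feature_class,
               cluster = cl, effect = unname(logfc), p = unname(p),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  th <- DE_THRESHOLDS[[feature_class]]
  res$significant <- abs(res$effect) > th$logfc & res$fdr < th$fdr
  rownames(res) <- NULL
  res
}

#' Euclidean tumor-map similarity
#'
#' Converts the Euclidean distance between samples' five-score vectors into
#' a similarity via `S = 1 / (1 + d)`. Identical score vectors give
#' similarity 1; the matrix is symmetric with unit diagonal and entries in
#' (0, 1]. This similarity matrix is the input layout for tumor-map style
#' sample embeddings.
#'
#' @param scores A [score_matrix()] or samples x features numeric matrix.
#' @return Symmetric samples x samples similarity matrix.
#' @export
tumor_map_similarity <- function(scores) {
  x <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  d <- as.matrix(stats::dist(x))
  1 / (1 + d)
}

#' Survival contrasts among clusters
#'
#' Overall log-rank test across all clusters plus a pairwise univariate Cox
#' table: for each ordered pair (row cluster vs column cluster) the hazard
#' ratio of the row cluster relative to the column cluster, with its Wald
#' p-value. Following the reporting convention of pan-cancer subtype
#' figures, pairs with p >= 0.05 are masked (`hr_shown = NA`) while the raw
#' estimates remain available.
#'
#' @param cluster_labels Cluster assignment per sample.
#' @param time Positive survival/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return List with `logrank` (list: `chisq`, `df`, `p`) and `pairwise`
#'   (data.frame: `row_cluster`, `col_cluster`, `hr`, `p`, `hr_shown`).
#' @export
survival_contrasts <- function(cluster_labels, time, event) {
  if (any(time <= 0)) fail("survival times must be positive")
  if (!all(event %in% c(0, 1))) fail("event must be 0/1")
  if (sum(event) == 0) fail("no events observed")
  clusters <- sort(unique(cluster_labels))
  if (length(clusters) < 2L) fail("need at least two clusters")
  grp <- factor(cluster_labels, levels = clusters)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  df <- length(clusters) - 1L
  logrank <- list(chisq = unname(sd_fit$chisq), df = df,
                  p = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE))
  pairs <- expand.grid(row_cluster = clusters, col_cluster = clusters,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$row_cluster != pairs$col_cluster, , drop = FALSE]
  est <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$row_cluster[i]; b <- pairs$col_cluster[i]
    sel <- cluster_labels %in% c(a, b)
    g <- factor(cluster_labels[sel], levels = c(b, a))  # column = reference
    fit <- survival::coxph(survival::Surv(time[sel], event[sel]) ~ g)
    s <- summary(fit)
    c(hr = unname(s$coefficients[1, "exp(coef)"]),
      p = unname(s$coefficients[1, "Pr(>|z|)"]))
  })
  pairwise <- cbind(pairs, do.call(rbind, est))
  pairwise$hr_shown <- ifelse(pairwise$p < 0.05, pairwise$hr, NA_real_)
  rownames(pairwise) <- NULL
  list(logrank = logrank, pairwise = pairwise)
}
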