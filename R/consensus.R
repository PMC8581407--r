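#' Resampled K-means consensus clustering of the score matrix
#'
#' Monti-style consensus clustering: for each resample, a fraction of
#' samples is drawn without replacement and partitioned by K-means
#' (Euclidean) for every K in `k_range`. The consensus matrix entry
#' `M(i, j)` is the number of times i and j co-clustered divided by the
#' number of times they were co-sampled. Final per-K labels come from
#' average-linkage hierarchical clustering of `1 - M` (the
#' ConsensusClusterPlus convention), not from a final K-means run.
#'
#' Diagnostics per K: mean within-cluster consensus per cluster, area under
#' the empirical CDF of the off-diagonal consensus values (computed exactly
#' as `1 - mean(M)` since entries lie in \[0, 1\]), relative delta area, and
#' average silhouette width of the final labels in score space.
#'
#' @param scores A [score_matrix()] or plain samples x features numeric matrix.
#' @param k_range Integer vector of K values to evaluate (default `2:8`).
#' @param resamples Number of subsampling iterations (default 500).
#' @param subsample_frac Fraction of samples drawn per iteration (default 0.8).
#' @param seed RNG seed; the whole result is reproducible from it.
#' @param nstart Random restarts per K-means run (default 20).
#' @param keep_log Record the per-resample subsample draws and K-means
#'   assignments (an audit log enabling independent recomputation of the
#'   consensus matrices); off by default to save memory.
#' @return An object of class `consensus_result` with fields `k_range`,
#'   `consensus` (list of per-K matrices), `cluster_consensus`, `cdf_area`,
#'   `delta_area`, `silhouette_avg`, `labels` (samples x K matrix),
#'   `chosen_k` (`NA` until [select_k()] is run), `seed`, `params`.
#' @export
consensus_cluster <- function(scores, k_range = 2:8, resamples = 500,
                              subsample_frac = 0.8, seed = 1, nstart = 20,
                              keep_log = FALSE) {
  x <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L) fail("k_range must start at 2 or above")
  if (max(k_range) > n / 3) fail("largest K (%d) exceeds n/3 = %.0f",
                                 max(k_range), n / 3)
  if (subsample_frac <= 0 || subsample_frac > 1) {
    fail("subsample_frac must lie in (0, 1]")
  }
  n_distinct <- nrow(unique(x))
  if (max(k_range) > n_distinct) {
    fail("K = %d exceeds the %d distinct points", max(k_range), n_distinct)
  }
  m <- ceiling(subsample_frac * n)
  set.seed(seed)
  draws <- lapply(seq_len(resamples), function(b) sort(sample.int(n, m)))

  co_sampled <- matrix(0L, n, n)
  co_clustered <- stats::setNames(
    lapply(k_range, function(k) matrix(0L, n, n)), as.character(k_range))
  log <- if (keep_log) vector("list", resamples)
  for (b in seq_len(resamples)) {
    idx <- draws[[b]]
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1L
    xb <- x[idx, , drop = FALSE]
    assignments <- list()
    for (k in k_range) {
      km <- stats::kmeans(xb, centers = k, nstart = nstart, iter.max = 50)
      if (keep_log) assignments[[as.character(k)]] <- km$cluster
      for (cl in seq_len(k)) {
        members <- idx[km$cluster == cl]
        co_clustered[[as.character(k)]][members, members] <-
          co_clustered[[as.character(k)]][members, members] + 1L
      }
    }
    if (keep_log) log[[b]] <- list(idx = idx, assignments = assignments)
  }

  sample_names <- rownames(x) %||% paste0("S", seq_len(n))
  consensus <- lapply(co_clustered, function(cc) {
    M <- cc / co_sampled
    M[co_sampled == 0L] <- NA_real_  # never co-sampled: flagged missing
    diag(M)[diag(co_sampled) > 0L] <- 1
    dimnames(M) <- list(sample_names, sample_names)
    M
  })

  labels <- matrix(NA_integer_, n, length(k_range),
                   dimnames = list(sample_names, as.character(k_range)))
  cluster_consensus <- list()
  cdf_area <- silhouette_avg <- stats::setNames(
    numeric(length(k_range)), as.character(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    M <- consensus[[as.character(k)]]
    D <- 1 - M
    D[is.na(D)] <- 1  # un-co-sampled pairs treated as maximally distant
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    lab <- stats::cutree(hc, k = k)
    labels[, i] <- lab
    cluster_consensus[[as.character(k)]] <- vapply(seq_len(k), function(cl) {
      members <- which(lab == cl)
      if (length(members) < 2L) return(1)
      sub <- M[members, members]
      mean(sub[upper.tri(sub)], na.rm = TRUE)
    }, numeric(1))
    off <- M[upper.tri(M)]
    off <- off[!is.na(off)]
    cdf_area[i] <- 1 - mean(off)  # exact area under the ECDF on [0, 1]
    silhouette_avg[i] <- silhouette_width(x, lab)$average
  }
  delta_area <- c(cdf_area[1],
                  if (length(k_range) > 1) diff(cdf_area) / cdf_area[-length(cdf_area)])
  names(delta_area) <- as.character(k_range)

  structure(list(k_range = k_range, consensus = consensus,
                 cluster_consensus = cluster_consensus,
                 cdf_area = cdf_area, delta_area = delta_area,
                 silhouette_avg = silhouette_avg, labels = labels,
                 chosen_k = NA_integer_, seed = seed, log = log,
                 params = list(resamples = resamples,
                               subsample_frac = subsample_frac,
                               nstart = nstart,
                               final_linkage = "average")),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over K =", paste(x$k_range, collapse = ", "), "\n")
  cat(sprintf("  %-3s %-9s %-11s %s\n", "K", "cdf_area", "delta_area",
              "silhouette"))
  for (i in seq_along(x$k_range)) {
    cat(sprintf("  %-3d %-9.3f %-11.3f %.3f\n", x$k_range[i],
                x$cdf_area[i], x$delta_area[i], x$silhouette_avg[i]))
  }
  if (!is.na(x$chosen_k)) cat("chosen K:", x$chosen_k, "\n")
  invisible(x)
}

#' Select the number of clusters from consensus diagnostics
#'
#' Codified elbow-plus-silhouette rule. A value of K qualifies when its
#' relative delta area exceeds `delta_floor` (K values beyond the elbow,
#' where adding a cluster raises the consensus-CDF area by less than the
#' floor, are treated as over-splits) and its average silhouette width
#' reaches `min_silhouette`. Among qualifying K the one with the highest
#' average silhouette width is chosen (ties favor the smaller K). If no K
#' qualifies — the null-structure case — the K with the highest silhouette
#' is returned with a warning. The decision trace (which K passed which
#' gate) is attached to the result.
#'
#' @param result A [consensus_cluster()] result.
#' @param min_silhouette Silhouette floor (default 0.25; unstructured
#'   Gaussian data yields averages well below this).
#' @param delta_floor Relative delta-area floor (default 0.05).
#' @return The chosen K (integer), with attribute `trace` (a data.frame).
#' @export
select_k <- function(result, min_silhouette = 0.25, delta_floor = 0.05) {
  stopifnot(inherits(result, "consensus_result"))
  trace <- data.frame(
    k = result$k_range,
    delta_area = unname(result$delta_area),
    silhouette = unname(result$silhouette_avg),
    pass_delta = unname(result$delta_area > delta_floor),
    pass_silhouette = unname(result$silhouette_avg >= min_silhouette)
  )
  trace$qualifies <- trace$pass_delta & trace$pass_silhouette
  if (any(trace$qualifies)) {
    cand <- trace[trace$qualifies, ]
    k <- cand$k[which.max(cand$silhouette)]
  } else {
    warning("no K passed the delta-area/silhouette gates; falling back to argmax silhouette",
            call. = FALSE)
    k <- trace$k[which.max(trace$silhouette)]
  }
  structure(as.integer(k), trace = trace)
}

#' Cluster labels at a given K
#'
#' @param result A [consensus_cluster()] result.
#' @param k K value (default the chosen one after [select_k()]).
#' @return Named integer vector of labels in `1..K`.
#' @export
consensus_labels <- function(result, k) {
  stopifnot(inherits(result, "consensus_result"))
  if (!as.character(k) %in% colnames(result$labels)) {
    fail("K = %s was not evaluated", k)
  }
  stats::setNames(result$labels[, as.character(k)], rownames(result$labels))
}

#' Silhouette widths for a labeled score matrix
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with Euclidean distances, where
#' `a(i)` is the mean distance of sample i to its own cluster and `b(i)` the
#' mean distance to the nearest other cluster. Samples in singleton clusters
#' get `s(i) = 0`.
#'
#' @param scores A [score_matrix()] or samples x features numeric matrix.
#' @param labels Integer/character cluster assignments, one per sample.
#' @return List with `widths` (per-sample numeric) and `average`.
#' @export
silhouette_width <- function(scores, labels) {
  x <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  labels <- as.vector(labels)
  if (length(labels) != nrow(x)) fail("one label per sample required")
  clusters <- unique(labels)
  if (length(clusters) < 2L) fail("silhouette needs at least 2 clusters")
  d <- as.matrix(stats::dist(x))
  widths <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)  # singleton cluster
    a <- mean(d[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(clusters[clusters != labels[i]], function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  names(widths) <- rownames(x)
  list(widths = widths, average = mean(widths))
}

#' Assign semantic inflammasome labels to six clusters
#'
#' Ranks cluster centroids by their IC (sensing) score: the bottom, middle
#' and top pairs become the `IC^Low`, `IC^Mid` and `IC^High` strata. Within
#' the Low pair clusters are discriminated by IL1B (`IL1B^Low` /
#' `IL1B^High`); within the Mid pair by whichever of CASP1 or IL18 dominates
#' the centroid (`CASP1^High` vs `IL18^High`); within the High pair by IL18
#' (`IL18^Low` / `IL18^High`). Cluster numbers 1..6 are re-assigned by
#' ascending IC centroid, then ascending IL18 within each stratum. An IC tie
#' between centroids is broken by the CASP1 centroid.
#'
#' With K other than 6 only numeric labels are returned (semantic labeling
#' is specific to the six-cluster solution) and a notice is emitted.
#'
#' @param scores A [score_matrix()] or samples x 5 matrix with the standard
#'   score columns.
#' @param labels Cluster assignments, one per sample.
#' @return A data.frame with one row per cluster: `cluster` (new 1..K
#'   number), `original` (input label), `semantic` (name or `NA`), and the
#'   five centroid columns; attribute `sample_labels` carries the re-numbered
#'   per-sample assignments and `sample_semantic` the per-sample names.
#' @export
label_clusters <- function(scores, labels) {
  x <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  if (!all(SCORE_NAMES %in% colnames(x))) {
    fail("score columns %s required", paste(SCORE_NAMES, collapse = ", "))
  }
  labels <- as.vector(labels)
  cl_ids <- sort(unique(labels))
  centroids <- t(vapply(cl_ids, function(cl) {
    colMeans(x[labels == cl, SCORE_NAMES, drop = FALSE])
  }, numeric(length(SCORE_NAMES))))
  rownames(centroids) <- cl_ids

  if (anyDuplicated(centroids[, "IC"])) {
    message("IC centroid tie broken by CASP1 centroid")
  }
  ic_order <- order(centroids[, "IC"], centroids[, "CASP1"])

  if (length(cl_ids) != 6L) {
    message(sprintf("%d clusters: semantic labeling applies only to K = 6, returning numeric labels",
                    length(cl_ids)))
    new_num <- order(ic_order)  # rank by IC
    out <- data.frame(cluster = new_num, original = cl_ids,
                      semantic = NA_character_, centroids,
                      check.names = FALSE, stringsAsFactors = FALSE)
    out <- out[order(out$cluster), , drop = FALSE]
    rownames(out) <- NULL
    map <- stats::setNames(new_num, cl_ids)
    attr(out, "sample_labels") <- unname(map[as.character(labels)])
    attr(out, "sample_semantic") <- rep(NA_character_, length(labels))
    return(out)
  }

  strata <- list(Low = ic_order[1:2], Mid = ic_order[3:4], High = ic_order[5:6])
  semantic <- character(6)
  new_order <- integer(0)
  for (st in names(strata)) {
    pair <- strata[[st]]
    pair <- pair[order(centroids[pair, "IL18"])]  # ascending IL18 numbering
    if (st == "Low") {
      by_il1b <- pair[order(centroids[pair, "IL1B"])]
      semantic[by_il1b[1]] <- "IC^Low IL1B^Low"
      semantic[by_il1b[2]] <- "IC^Low IL1B^High"
    } else if (st == "Mid") {
      # dominance contrast: which centroid leans CASP1 vs IL18
      lean <- centroids[pair, "CASP1"] - centroids[pair, "IL18"]
      semantic[pair[which.max(lean)]] <- "IC^Mid CASP1^High"
      semantic[pair[which.min(lean)]] <- "IC^Mid IL18^High"
    } else {
      by_il18 <- pair[order(centroids[pair, "IL18"])]
      semantic[by_il18[1]] <- "IC^High IL18^Low"
      semantic[by_il18[2]] <- "IC^High IL18^High"
    }
    new_order <- c(new_order, pair)
  }
  new_num <- integer(6)
  new_num[new_order] <- seq_len(6)
  out <- data.frame(cluster = new_num, original = cl_ids,
                    semantic = semantic, centroids,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  num_map <- stats::setNames(new_num, cl_ids)
  sem_map <- stats::setNames(semantic, cl_ids)
  attr(out, "sample_labels") <- unname(num_map[as.character(labels)])
  attr(out, "sample_semantic") <- unname(sem_map[as.character(labels)])
  out
}
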