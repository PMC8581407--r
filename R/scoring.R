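#' Parameters for single-sample GSEA scoring
#'
#' @param alpha Rank-weight exponent applied to the expression ranks of
#'   in-set genes; `0.25` is the conventional ssGSEA exponent, `0` gives the
#'   unweighted Kolmogorov-Smirnov-style running sum.
#' @param tie_policy How tied expression values are ranked: `"average"`
#'   (deterministic, default), `"min"`, or `"random"` (requires `seed`).
#' @param normalize `"none"` (raw enrichment score) or
#'   `"minmax_across_samples"` (scores rescaled to \[0, 1\] across the samples
#'   of one call; introduces cross-sample coupling).
#' @param seed RNG seed used only by `tie_policy = "random"`.
#' @return An object of class `score_params`.
#' @export
score_params <- function(alpha = 0.25,
                         tie_policy = c("average", "min", "random"),
                         normalize = c("none", "minmax_across_samples"),
                         seed = NULL) {
  tie_policy <- match.arg(tie_policy)
  normalize <- match.arg(normalize)
  if (alpha < 0) fail("alpha must be >= 0")
  if (tie_policy == "random" && is.null(seed)) {
    fail("tie_policy 'random' needs a seed")
  }
  structure(list(alpha = alpha, tie_policy = tie_policy,
                 normalize = normalize, seed = seed),
            class = "score_params")
}

# per-sample running-sum enrichment for one set given precomputed descending
# order and ascending ranks of one sample
.es_one <- function(ord, rk, in_set, alpha, n_out) {
  hit <- in_set[ord]
  w <- (rk[ord]^alpha) * hit
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!hit) / n_out
  sum(p_in - p_out)
}

#' Single-sample GSEA enrichment scores
#'
#' For each sample, genes are ranked by expression (descending; ties per
#' `tie_policy`). Walking down the ranked list, in-set genes contribute their
#' rank raised to `alpha` (normalized to the total in-set weight) and
#' out-of-set genes contribute a uniform step; the enrichment score is the
#' sum over the whole list of (cumulative in-set weight fraction minus
#' cumulative out-of-set count fraction). Being rank-based, the score is
#' invariant to any strictly increasing transform of a sample's values.
#'
#' Set members absent from the matrix are dropped (per-call intersection
#' with the gene universe); if more than half of the set is absent a warning
#' is raised, and if no member is present the call errors.
#'
#' @param expr An [expression_matrix()].
#' @param set A [gene_set()] (or plain character vector of symbols).
#' @param params A [score_params()].
#' @return Named numeric vector of per-sample enrichment scores.
#' @export
ssgsea_score <- function(expr, set, params = score_params()) {
  stopifnot(inherits(expr, "expression_matrix"))
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)
  set_name <- if (inherits(set, "gene_set")) set$name else "<ad hoc set>"
  v <- expr$values
  present <- intersect(members, rownames(v))
  if (length(present) == 0L) {
    fail("no member of set '%s' is present in the expression matrix", set_name)
  }
  if (length(present) < length(members) / 2) {
    warning(sprintf("set '%s': %d of %d members absent from the matrix",
                    set_name, length(members) - length(present),
                    length(members)), call. = FALSE)
  }
  if (length(present) == nrow(v)) {
    fail("set '%s' covers the whole gene universe", set_name)
  }
  in_set <- rownames(v) %in% present
  n_out <- sum(!in_set)
  tie_method <- switch(params$tie_policy, average = "average", min = "min",
                       random = "random")
  if (params$tie_policy == "random") set.seed(params$seed)
  es <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    rk <- rank(x, ties.method = tie_method)
    ord <- order(rk, decreasing = TRUE)
    .es_one(ord, rk, in_set, params$alpha, n_out)
  }, numeric(1))
  names(es) <- colnames(v)
  if (params$normalize == "minmax_across_samples") {
    rng <- range(es)
    es <- if (diff(rng) == 0) rep(0, length(es)) else (es - rng[1]) / diff(rng)
    names(es) <- colnames(v)
  }
  es
}

#' Directional composite score
#'
#' Activity readout for a post-translationally regulated signaling node: the
#' enrichment of its up-regulated target set minus the enrichment of its
#' down-regulated target set, per sample.
#'
#' @param pos,neg Named per-sample score vectors over the same samples.
#' @return `pos - neg`, named.
#' @export
composite_score <- function(pos, neg) {
  if (length(pos) != length(neg) || !identical(names(pos), names(neg))) {
    fail("positive and negative score vectors are not indexed by the same samples")
  }
  pos - neg
}

#' Compute the five-score inflammasome matrix
#'
#' `IC` is the plain ssGSEA enrichment of the core sensing set;
#' `CASP1`, `GSDMD`, `IL1B` and `IL18` are composites (up-set score minus
#' down-set score). With `standardize = TRUE` (the default, and the form
#' used for clustering) each column is z-scored across samples and the
#' transform recorded, so downstream consumers can re-apply it to external
#' cohorts rather than refitting.
#'
#' @param expr An [expression_matrix()].
#' @param scheme A [signature_scheme()].
#' @param params A [score_params()].
#' @param standardize Z-score each column across samples (default `TRUE`).
#' @return An object of class `score_matrix`: list with `scores` (samples x 5
#'   matrix, columns `IC, CASP1, GSDMD, IL1B, IL18`), `scaling` (either
#'   `"none"` or a list with `center`/`scale`), `params`, and
#'   `scheme_fingerprint`.
#' @export
score_matrix <- function(expr, scheme, params = score_params(),
                         standardize = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(scheme, "signature_scheme"))
  one <- function(set, score_name) {
    tryCatch(ssgsea_score(expr, set, params),
             error = function(e) fail("score %s: %s", score_name,
                                      conditionMessage(e)))
  }
  cols <- lapply(SCORE_NAMES, function(nm) {
    sc <- scheme$scores[[nm]]
    pos <- one(sc$positive, nm)
    if (is.null(sc$negative)) pos else
      composite_score(pos, one(sc$negative, nm))
  })
  scores <- do.call(cbind, cols)
  colnames(scores) <- SCORE_NAMES
  rownames(scores) <- colnames(expr$values)
  scaling <- "none"
  if (standardize) {
    ctr <- colMeans(scores)
    scl <- apply(scores, 2, stats::sd)
    if (any(scl == 0)) fail("cannot standardize: constant score column")
    scores <- scale(scores, center = ctr, scale = scl)
    attr(scores, "scaled:center") <- NULL
    attr(scores, "scaled:scale") <- NULL
    scaling <- list(center = ctr, scale = scl)
  }
  structure(list(scores = scores, scaling = scaling, params = params,
                 scheme_fingerprint = scheme_fingerprint(scheme)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d samples x %d scores (%s)\n",
              nrow(x$scores), ncol(x$scores),
              if (identical(x$scaling, "none")) "raw" else "z-scored"))
  invisible(x)
}

#' Write a score matrix as TSV with a JSON sidecar
#'
#' The sidecar records the scoring parameters, any standardization applied
#' and the scheme fingerprint, so the matrix can be audited and matched to a
#' trained predictor.
#'
#' @param sm A [score_matrix()].
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "score_matrix"))
  df <- data.frame(sample = rownames(sm$scores), sm$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$sample), , drop = FALSE]
  write_tsv_plain(df, path)
  meta <- list(params = unclass(sm$params), scaling = sm$scaling,
               scheme_fingerprint = sm$scheme_fingerprint)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
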