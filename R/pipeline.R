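#' Run configuration
#'
#' A single object holding every tunable of a pipeline run. One top-level
#' seed fans out deterministically into named substreams (simulation,
#' resampling, splitting) so stages can be re-run independently yet
#' reproducibly; the configuration is echoed verbatim into the output
#' directory so any run can be reproduced byte-for-byte from
#' `(inputs, config)`.
#'
#' @param seed Top-level RNG seed.
#' @param alpha ssGSEA rank-weight exponent.
#' @param standardize Z-score the score columns before clustering.
#' @param k_range K values evaluated by consensus clustering.
#' @param resamples Consensus resampling iterations.
#' @param subsample_frac Consensus subsample fraction.
#' @param min_silhouette,delta_floor [select_k()] gates.
#' @param svm_cost SVM regularization constant.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, alpha = 0.25, standardize = TRUE,
                       k_range = 2:8, resamples = 500, subsample_frac = 0.8,
                       min_silhouette = 0.25, delta_floor = 0.05,
                       svm_cost = 1, out_dir = NULL) {
  structure(list(seed = as.integer(seed), alpha = alpha,
                 standardize = standardize, k_range = k_range,
                 resamples = resamples, subsample_frac = subsample_frac,
                 min_silhouette = min_silhouette, delta_floor = delta_floor,
                 svm_cost = svm_cost, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    fail("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

# deterministic substream seeds derived from the top-level seed; kept below
# 2^31 by construction
substream_seed <- function(seed, stream) {
  offsets <- c(simulate = 101L, resample = 211L, split = 307L, features = 401L)
  if (!stream %in% names(offsets)) fail("unknown RNG substream '%s'", stream)
  (as.integer(seed) * 1009L + offsets[[stream]]) %% 2147483647L
}

#' Run the full subtyping pipeline on a cohort
#'
#' Scores the expression matrix under the scheme, consensus-clusters the
#' five-score matrix, selects K, labels clusters (semantically when K = 6),
#' characterizes them (tumor-type enrichment; survival contrasts when
#' metadata carries `time`/`event`), validates the six classifiers and
#' trains the SVM predictor. When `config$out_dir` is set, every table is
#' written with deterministic ordering together with the echoed
#' configuration, so repeated runs are byte-identical.
#'
#' @param expr An [expression_matrix()] with optional metadata columns
#'   `tumor_type`, `time`, `event`.
#' @param scheme A [signature_scheme()] (default: the packaged one).
#' @param config A [run_config()].
#' @return List with `scores`, `consensus`, `chosen_k`, `labels`,
#'   `labeling`, `enrichment`, `survival`, `validation`, `model`.
#' @export
run_pipeline <- function(expr, scheme = default_scheme(),
                         config = run_config()) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(config, "run_config"))
  params <- score_params(alpha = config$alpha)
  sm_raw <- score_matrix(expr, scheme, params, standardize = FALSE)
  sm <- score_matrix(expr, scheme, params, standardize = config$standardize)
  cc <- consensus_cluster(sm, k_range = config$k_range,
                          resamples = config$resamples,
                          subsample_frac = config$subsample_frac,
                          seed = substream_seed(config$seed, "resample"))
  k <- select_k(cc, min_silhouette = config$min_silhouette,
                delta_floor = config$delta_floor)
  labs <- consensus_labels(cc, k)
  labeling <- label_clusters(sm, labs)
  final_labels <- stats::setNames(attr(labeling, "sample_labels"), names(labs))

  md <- expr$metadata
  enrichment <- NULL
  if (!is.null(md) && "tumor_type" %in% names(md)) {
    enrichment <- hypergeom_enrichment(final_labels, md$tumor_type)
  }
  surv <- NULL
  if (!is.null(md) && all(c("time", "event") %in% names(md))) {
    surv <- survival_contrasts(final_labels, md$time, md$event)
  }
  validation <- two_layer_validate(sm, final_labels,
                                   seed = substream_seed(config$seed, "split"))
  model <- train_predictor(sm_raw, final_labels, cost = config$svm_cost)

  result <- list(scores = sm, consensus = cc, chosen_k = as.integer(k),
                 labels = final_labels, labeling = labeling,
                 enrichment = enrichment, survival = surv,
                 validation = validation, model = model)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

# write the tabular outputs of a pipeline run with deterministic ordering
write_pipeline_outputs <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(config)
  cfg$k_range <- as.integer(cfg$k_range)
  cfg$out_dir <- NULL  # location is self-evident; keeps runs byte-comparable
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write_score_matrix(result$scores, file.path(dir, "scores.tsv"))
  labs <- data.frame(sample = names(result$labels),
                     cluster = unname(result$labels),
                     semantic = attr(result$labeling, "sample_semantic"),
                     stringsAsFactors = FALSE)
  write_tsv_plain(labs[order(labs$sample), ], file.path(dir, "labels.tsv"))
  diag <- data.frame(k = result$consensus$k_range,
                     cdf_area = unname(result$consensus$cdf_area),
                     delta_area = unname(result$consensus$delta_area),
                     silhouette = unname(result$consensus$silhouette_avg))
  write_tsv_plain(diag, file.path(dir, "consensus_diagnostics.tsv"))
  if (!is.null(result$enrichment)) {
    write_tsv_plain(result$enrichment, file.path(dir, "enrichment.tsv"))
  }
  if (!is.null(result$survival)) {
    write_tsv_plain(result$survival$pairwise, file.path(dir, "cox_pairwise.tsv"))
    jsonlite::write_json(result$survival$logrank,
                         file.path(dir, "logrank.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_validation_report(result$validation, file.path(dir, "validation.json"))
  invisible(dir)
}

#' Collate the outputs of a pipeline run into one summary
#'
#' Reads the tables a [run_pipeline()] call wrote to its output directory
#' and aggregates the headline quantities (cluster sizes, chosen K,
#' diagnostics, top enrichments, log-rank test, classifier accuracies) into
#' a single JSON document.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @param path Output JSON path (default `summary.json` inside `out_dir`).
#' @return The summary list, invisibly.
#' @export
report_summary <- function(out_dir, path = file.path(out_dir, "summary.json")) {
  labs <- read_tsv_plain(file.path(out_dir, "labels.tsv"))
  diag <- read_tsv_plain(file.path(out_dir, "consensus_diagnostics.tsv"))
  summary <- list(
    n_samples = nrow(labs),
    cluster_sizes = as.list(table(labs$cluster)),
    diagnostics = diag
  )
  enr_path <- file.path(out_dir, "enrichment.tsv")
  if (file.exists(enr_path)) {
    enr <- read_tsv_plain(enr_path)
    summary$top_enrichment <- utils::head(enr[order(enr$fdr), ], 10)
  }
  lr_path <- file.path(out_dir, "logrank.json")
  if (file.exists(lr_path)) summary$logrank <- jsonlite::read_json(lr_path)
  val_path <- file.path(out_dir, "validation.json")
  if (file.exists(val_path)) summary$validation <- jsonlite::read_json(val_path)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(summary)
}
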