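ALGORITHMS <- c("CART", "LR", "LDA", "KNN", "NB", "SVM")

# fit/predict wrappers with a uniform interface; train/test are plain
# data.frames of score columns, cl a factor
.fit_predict <- function(algorithm, train, cl_train, test) {
  switch(algorithm,
    CART = {
      fit <- rpart::rpart(y ~ ., data = cbind(train, y = cl_train),
                          method = "class")
      predict(fit, test, type = "class")
    },
    LR = {
      fit <- nnet::multinom(y ~ ., data = cbind(train, y = cl_train),
                            trace = FALSE, maxit = 200)
      predict(fit, test)
    },
    LDA = {
      fit <- MASS::lda(y ~ ., data = cbind(train, y = cl_train))
      predict(fit, test)$class
    },
    KNN = class::knn(train, test, cl_train, k = 5),
    NB = {
      fit <- e1071::naiveBayes(train, cl_train)
      predict(fit, test)
    },
    SVM = {
      fit <- .fit_svm(train, cl_train)
      predict(fit, test)
    },
    fail("unknown algorithm '%s'", algorithm)
  )
}

.fit_svm <- function(train, cl_train, cost = 1) {
  tab <- table(cl_train)
  cw <- stats::setNames(length(cl_train) / (nlevels(cl_train) * as.numeric(tab)),
                        names(tab))  # balanced class weights
  e1071::svm(x = as.matrix(train), y = cl_train, kernel = "radial",
             cost = cost, class.weights = cw, scale = FALSE)
}

# stratified fold ids: within each class, samples are dealt round-robin into
# folds after a seeded shuffle
.stratified_folds <- function(cl, n_folds) {
  fold <- integer(length(cl))
  for (lev in levels(cl)) {
    idx <- sample(which(cl == lev))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Two-layer validation of six subtype classifiers
#'
#' Compares CART, multinomial logistic regression (LR), LDA, KNN, Gaussian
#' naive Bayes (NB) and an RBF-kernel SVM on the five-score matrix. Layer
#' one: stratified five-fold cross-validation on a stratified 80% training
#' split. Layer two: accuracy on the held-out 20% validation split. The
#' chosen algorithm is the one with the highest holdout accuracy (ties
#' broken by CV accuracy).
#'
#' @param scores A [score_matrix()] or samples x features numeric matrix.
#' @param labels Cluster assignment per sample (from consensus clustering).
#' @param seed RNG seed driving the split and fold assignment.
#' @param holdout_frac Validation fraction (default 0.2).
#' @param n_folds Cross-validation folds (default 5).
#' @return An object of class `validation_report`: list with `algorithms`,
#'   `cv_accuracy`, `holdout_accuracy` (named numeric vectors), `chosen`,
#'   `split_seed`, `n_train`, `n_holdout`.
#' @export
two_layer_validate <- function(scores, labels, seed = 1, holdout_frac = 0.2,
                               n_folds = 5) {
  x <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  cl <- factor(labels)
  if (nrow(x) != length(cl)) fail("one label per sample required")
  if (any(table(cl) < 6)) fail("each class needs >= 6 samples")
  df <- as.data.frame(x)
  set.seed(seed)
  holdout <- unlist(lapply(levels(cl), function(lev) {
    idx <- which(cl == lev)
    sample(idx, max(1L, round(holdout_frac * length(idx))))
  }))
  train_idx <- setdiff(seq_len(nrow(df)), holdout)
  if (nlevels(droplevels(cl[train_idx])) < nlevels(cl)) {
    fail("a class is absent from the training split")
  }

  fold <- .stratified_folds(droplevels(cl[train_idx]), n_folds)
  cv_accuracy <- vapply(ALGORITHMS, function(alg) {
    correct <- vapply(seq_len(n_folds), function(f) {
      tr <- train_idx[fold != f]; te <- train_idx[fold == f]
      pred <- .fit_predict(alg, df[tr, , drop = FALSE], droplevels(cl[tr]),
                           df[te, , drop = FALSE])
      sum(as.character(pred) == as.character(cl[te]))
    }, numeric(1))
    sum(correct) / length(train_idx)
  }, numeric(1))
  holdout_accuracy <- vapply(ALGORITHMS, function(alg) {
    pred <- .fit_predict(alg, df[train_idx, , drop = FALSE],
                         droplevels(cl[train_idx]),
                         df[holdout, , drop = FALSE])
    mean(as.character(pred) == as.character(cl[holdout]))
  }, numeric(1))

  best <- which(holdout_accuracy == max(holdout_accuracy))
  chosen <- ALGORITHMS[best[which.max(cv_accuracy[best])]]
  structure(list(algorithms = ALGORITHMS, cv_accuracy = cv_accuracy,
                 holdout_accuracy = holdout_accuracy, chosen = chosen,
                 split_seed = seed, n_train = length(train_idx),
                 n_holdout = length(holdout)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report (split seed", x$split_seed, ")\n")
  tab <- data.frame(algorithm = x$algorithms,
                    cv_accuracy = round(x$cv_accuracy, 4),
                    holdout_accuracy = round(x$holdout_accuracy, 4))
  print(tab, row.names = FALSE)
  cat("chosen:", x$chosen, "\n")
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report A [two_layer_validate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Train the subtype predictor
#'
#' Fits the shipped classifier (RBF-kernel SVM, cost 1, class-balanced
#' weights) on all provided samples. The model stores the z-standardization
#' of the training scores and the fingerprint of the signature scheme the
#' scores were computed under; prediction on external cohorts re-applies the
#' stored transform instead of refitting it, and refuses score matrices
#' produced under a different scheme.
#'
#' @param scores A raw (unstandardized) [score_matrix()]; a standardized one
#'   is accepted and its recorded transform reused.
#' @param labels Cluster labels (numeric or semantic) per sample.
#' @param cost SVM regularization constant (default 1).
#' @return An object of class `cluster_model`: list with `fingerprint`,
#'   `scaling`, `fit`, `classes`, `cost`, `kernel`.
#' @export
train_predictor <- function(scores, labels, cost = 1) {
  stopifnot(inherits(scores, "score_matrix"))
  cl <- factor(labels)
  if (nlevels(cl) < 2L) fail("training needs at least two classes")
  if (identical(scores$scaling, "none")) {
    ctr <- colMeans(scores$scores)
    scl <- apply(scores$scores, 2, stats::sd)
    if (any(scl == 0)) fail("constant score column; cannot standardize")
    x <- scale(scores$scores, center = ctr, scale = scl)
    scaling <- list(center = ctr, scale = scl)
  } else {
    x <- scores$scores  # already standardized; reuse the recorded transform
    scaling <- scores$scaling
  }
  fit <- .fit_svm(as.data.frame(x), cl, cost = cost)
  structure(list(fingerprint = scores$scheme_fingerprint, scaling = scaling,
                 fit = fit, classes = levels(cl), cost = cost,
                 kernel = "radial"),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: RBF SVM over", length(x$classes), "classes\n")
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  cat("scheme fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Predict inflammasome clusters for an external cohort
#'
#' Applies a trained [train_predictor()] model to a score matrix from an
#' external cohort. The external scores must be raw (unstandardized) and
#' computed under the same signature scheme as the training data (checked
#' via fingerprint); the training standardization is re-applied, never
#' refit, so no information flows from the external cohort into the scaling.
#'
#' @param model A `cluster_model`.
#' @param external_scores A raw [score_matrix()] for the external cohort.
#' @return List with `labels` (named character vector of predicted classes)
#'   and `decision_values` (samples x class-pair SVM decision values).
#' @export
predict_clusters <- function(model, external_scores) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(external_scores, "score_matrix"))
  if (!identical(model$fingerprint, external_scores$scheme_fingerprint)) {
    fail("scheme fingerprint mismatch: external scores were computed under a different signature scheme")
  }
  if (!identical(external_scores$scaling, "none")) {
    fail("external scores must be raw: the training standardization is re-applied, not refit")
  }
  x <- scale(external_scores$scores, center = model$scaling$center,
             scale = model$scaling$scale)
  pred <- predict(model$fit, as.matrix(x), decision.values = TRUE)
  labels <- stats::setNames(as.character(pred), rownames(x))
  list(labels = labels,
       decision_values = attr(pred, "decision.values"))
}

#' Save / load a cluster model
#'
#' Serializes the model (scheme fingerprint, scaling, SVM parameters) so
#' that a reloaded model reproduces predictions exactly.
#'
#' @param model A `cluster_model`.
#' @param path File path.
#' @return `path` invisibly ([save_cluster_model()]); the model
#'   ([load_cluster_model()]).
#' @export
save_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cluster_model
#' @export
load_cluster_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cluster_model")) fail("'%s' is not a cluster_model", path)
  model
}
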