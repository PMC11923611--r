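#' Train the gradient-boosted behaviour classifier
#'
#' Fits a multi-class boosted-tree model (xgboost) mapping 50-feature
#' window vectors to behaviours. Defaults are 300 trees of depth 3 with
#' learning rate 0.1, single-threaded so that results are reproducible
#' from the seed.
#'
#' @param features numeric matrix (windows x features), no missing values.
#' @param labels character vector of behaviour names, one per row of
#'   `features`.
#' @param params list with elements `nrounds`, `max_depth`, `eta`.
#' @param seed integer seed.
#' @return object of class `behaviour_classifier`.
#' @export
train_classifier <- function(features, labels,
                             params = list(nrounds = 300, max_depth = 3,
                                           eta = 0.1),
                             seed = 1) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite")
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to train")
  y <- match(labels, classes) - 1L
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(classes),
                  max_depth = params$max_depth, eta = params$eta,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(features, label = y),
    nrounds = params$nrounds, verbose = 0
  )
  structure(
    list(booster = booster, classes = classes,
         feature_names = colnames(features), n_features = ncol(features),
         params = params, seed = seed),
    class = "behaviour_classifier"
  )
}

#' Predict behaviours (and categories) for feature vectors
#'
#' @param object a `behaviour_classifier`.
#' @param features numeric matrix with the same columns the model was
#'   trained on; a single vector is treated as one window.
#' @param ... unused.
#' @return data.frame with columns `behaviour` and `category`.
#' @export
predict.behaviour_classifier <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != object$n_features) {
    stop("feature vectors have length ", ncol(features),
         " but the model expects ", object$n_features)
  }
  pr <- predict(object$booster, xgboost::xgb.DMatrix(features))
  if (is.null(dim(pr))) {
    pr <- matrix(pr, ncol = length(object$classes), byrow = TRUE)
  }
  beh <- object$classes[max.col(pr, ties.method = "first")]
  data.frame(behaviour = beh, category = map_to_categories(beh),
             stringsAsFactors = FALSE)
}

#' Leave-individuals-out cross-validation of the classifier
#'
#' Evaluates classification accuracy with folds that partition
#' individuals, so no individual contributes windows to both the training
#' and the test side of any fold — the appropriate guard against
#' pseudo-replication when windows within an individual are correlated.
#'
#' @param features numeric matrix (windows x features).
#' @param labels character vector of behaviours.
#' @param group_ids individual id per window; folds split these ids.
#' @param n_folds number of folds (default 5; must not exceed the number
#'   of distinct ids).
#' @param seed integer seed for fold assignment and training.
#' @param params hyperparameters passed to [train_classifier()].
#' @return an evaluation report: list with the out-of-fold
#'   `confusion_behaviour` and `confusion_category` matrices (rows = truth),
#'   `accuracy_behaviour`, `accuracy_category`, `per_behaviour_accuracy`,
#'   and the `fold` assignment per window.
#' @export
evaluate_grouped_cv <- function(features, labels, group_ids, n_folds = 5,
                                seed = 1,
                                params = list(nrounds = 300, max_depth = 3,
                                              eta = 0.1)) {
  features <- as.matrix(features)
  ids <- unique(group_ids)
  if (length(ids) < n_folds) {
    stop("fewer distinct individuals (", length(ids), ") than folds (",
         n_folds, ")")
  }
  set.seed(seed)
  id_fold <- sample(rep_len(seq_len(n_folds), length(ids)))
  names(id_fold) <- ids
  fold <- id_fold[as.character(group_ids)]

  pred <- character(length(labels))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    model <- train_classifier(features[!test, , drop = FALSE], labels[!test],
                              params = params, seed = seed + f)
    pred[test] <- predict(model, features[test, , drop = FALSE])$behaviour
  }
  beh_levels <- sort(unique(c(labels, pred)))
  confusion_behaviour <- table(
    truth = factor(labels, beh_levels),
    predicted = factor(pred, beh_levels)
  )
  cat_levels <- category_levels()
  confusion_category <- table(
    truth = factor(map_to_categories(labels), cat_levels),
    predicted = factor(map_to_categories(pred), cat_levels)
  )
  per_beh <- diag(confusion_behaviour) / pmax(rowSums(confusion_behaviour), 1)
  list(
    confusion_behaviour = confusion_behaviour,
    confusion_category = confusion_category,
    accuracy_behaviour = mean(pred == labels),
    accuracy_category = mean(map_to_categories(pred) ==
                               map_to_categories(labels)),
    per_behaviour_accuracy = per_beh,
    fold = unname(fold)
  )
}
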