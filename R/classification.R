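#' Fit a random-forest exercise classifier
#'
#' 100 trees, Gini splits, `sqrt(p)` candidate features per split, unlimited
#' depth, bootstrap resampling — the conventional defaults, pinned explicitly
#' for reproducibility. Per-class probability is the tree-vote fraction.
#'
#' @param X `feature_tbl` or numeric matrix (engineered features or FCN
#'   embeddings).
#' @param y Class labels; at least two classes (map labels with
#'   [apply_grouping()] *before* fitting to train at a coarser level).
#' @param seed RNG seed.
#' @return An `exercise_rf` model.
#' @export
fit_random_forest <- function(X, y, seed = 0L) {
  M <- if (is.matrix(X)) X else feature_values(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes to fit a classifier")
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = M, y = y, ntree = 100L, mtry = max(1L, floor(sqrt(ncol(M))))
  )
  structure(list(model = rf, classes = levels(y)), class = "exercise_rf")
}

#' @export
predict.exercise_rf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  M <- if (is.matrix(newdata)) newdata else feature_values(newdata)
  if (type == "prob") {
    unclass(predict(object$model, M, type = "prob"))
  } else {
    as.character(predict(object$model, M, type = "response"))
  }
}

#' @export
glance.exercise_rf <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), ntree = x$model$ntree,
                 oob_error = x$model$err.rate[x$model$ntree, "OOB"])
}

#' Patient-specific k-nearest-neighbour classification
#'
#' Labels each query window with the majority class among its
#' `min(k, |support|)` nearest support rows (Euclidean distance); when the
#' majority is tied, the class of the single nearest neighbour wins. The
#' support set is the patient's own second-to-last supervised session,
#' embedded by a feature extractor fitted on the training split, so the
#' classifier sees only that patient's technique.
#'
#' @param support `feature_tbl`/matrix of support windows.
#' @param support_labels Class label of each support row (defaults to the
#'   `label` column of a `feature_tbl` support).
#' @param query `feature_tbl`/matrix of windows to classify.
#' @param k Neighbour count (3).
#' @return Character vector of predicted labels, one per query row.
#' @export
patient_knn_classify <- function(support, query, support_labels = NULL, k = 3L) {
  S <- if (is.matrix(support)) support else feature_values(support)
  if (is.null(support_labels) && !is.matrix(support)) {
    support_labels <- support$label
  }
  stopifnot(length(support_labels) == nrow(S))
  if (nrow(S) == 0L) stop("empty support set; exclude this record upstream")
  Q <- if (is.matrix(query)) query else feature_values(query)
  k <- min(k, nrow(S))
  D2 <- pairwise_dist2(Q, S)
  vapply(seq_len(nrow(Q)), function(i) {
    nn <- order(D2[i, ])[seq_len(k)]
    votes <- table(support_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else as.character(support_labels[nn[1L]])
  }, character(1L))
}
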