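#' Out-of-distribution detectors
#'
#' All detectors share one convention: the score is OOD-ness (higher = more
#' likely non-exercise) and a window is kept as exercise iff
#' `score <= threshold`. Thresholds are calibrated with
#' [calibrate_detector()] under a minimum-sensitivity constraint (default
#' 0.90) so that exercise is rarely discarded.
#'
#' Families:
#' * `kmeans`: unsupervised; score is the Euclidean distance to the nearest
#'   of `n_clusters` KMeans centroids fitted on in-distribution training
#'   features (engineered or embedding).
#' * `softmax`: score is `1 - max` softmax probability of an FCN trained on
#'   in-distribution classes only (low confidence = OOD).
#' * `patient_knn`: patient-specific; score is the mean Euclidean distance to
#'   the `k = 3` nearest rows of the patient's own support session.
#' * `proxy_*`: a proxy non-exercise class (activities of daily living,
#'   size-matched to the in-distribution data) is added as an extra training
#'   class, turning OOD detection into supervised classification; the score
#'   is the predicted probability of the proxy class (for the `patient_knn`
#'   base, the fraction of the `k` nearest support rows that are proxy).
#'
#' @name ood_detectors
NULL

new_detector <- function(kind, fields) {
  structure(c(list(kind = kind, threshold = NULL, calibration = NULL), fields),
            class = "ood_detector")
}

#' @export
print.ood_detector <- function(x, ...) {
  cat(sprintf("<ood_detector %s> threshold: %s\n", x$kind,
              if (is.null(x$threshold)) "uncalibrated"
              else signif(x$threshold, 4)))
  invisible(x)
}

pairwise_dist2 <- function(Q, S) {
  d2 <- outer(rowSums(Q^2), rep(1, nrow(S))) +
    outer(rep(1, nrow(Q)), rowSums(S^2)) - 2 * Q %*% t(S)
  pmax(d2, 0)
}

#' Fit a KMeans distance detector
#'
#' @param X `feature_tbl` or numeric matrix of in-distribution training
#'   features (exercise windows only).
#' @param n_clusters Number of centroids; conventionally the number of
#'   in-distribution classes under the active grouping.
#' @param seed RNG seed (10 restarts).
#' @return An uncalibrated `ood_detector` of kind `"kmeans"`.
#' @export
fit_kmeans_detector <- function(X, n_clusters, seed = 0L) {
  M <- if (is.matrix(X)) X else feature_values(X)
  if (n_clusters < 1L || n_clusters > nrow(M)) {
    stop("parameter error: n_clusters must be in [1, rows]")
  }
  set.seed(seed)
  km <- kmeans(M, centers = n_clusters, nstart = 10L, iter.max = 100L)
  new_detector("kmeans", list(centers = km$centers))
}

#' Fit the softmax-confidence detector
#'
#' @param model An `fcn_model` trained on in-distribution classes only.
#' @return An uncalibrated `ood_detector` of kind `"softmax"`.
#' @export
fit_softmax_detector <- function(model) {
  stopifnot(inherits(model, "fcn_model"))
  new_detector("softmax", list(model = model))
}

#' Fit a patient-specific KNN distance detector
#'
#' The support set is the patient's most recent supervised session, embedded
#' with a feature extractor fitted on the training split. The score of a
#' query window is its mean Euclidean distance to the `min(k, |support|)`
#' nearest support rows.
#'
#' @param support `feature_tbl` or matrix of the patient's support windows.
#' @param k Neighbour count (3).
#' @return An uncalibrated `ood_detector` of kind `"patient_knn"`.
#' @export
fit_patient_knn_detector <- function(support, k = 3L) {
  S <- if (is.matrix(support)) support else feature_values(support)
  if (nrow(S) == 0L) stop("empty support set; exclude this record upstream")
  if (nrow(S) < k) {
    warning("support has ", nrow(S), " rows < k = ", k, "; using all of them")
  }
  new_detector("patient_knn", list(support = S, k = as.integer(k)))
}

#' Fit a proxy-class supervised detector
#'
#' @param X Training features (`feature_tbl`/matrix) for bases
#'   `random_forest` and `patient_knn`, or a [window_set()] for base `fcn`.
#' @param y Labels: exercise classes plus [ood_label()] rows for the proxy
#'   windows (for `window_set` input, defaults to its `label` column).
#' @param base `"random_forest"`, `"fcn"` or `"patient_knn"`.
#' @param k Neighbours for the `patient_knn` base.
#' @param match_size Subsample proxy rows down to the in-distribution row
#'   count when they exceed it (seeded), mirroring a size-matched proxy class.
#' @param seed RNG seed.
#' @param fcn_cfg [fcn_config()] for the `fcn` base.
#' @return An uncalibrated `ood_detector` of kind `proxy_<base>`.
#' @export
fit_proxy_detector <- function(X, y = NULL, base = c("random_forest", "fcn", "patient_knn"),
                               k = 3L, match_size = TRUE, seed = 0L,
                               fcn_cfg = fcn_config()) {
  base <- match.arg(base)
  if (is.null(y) && inherits(X, "window_set")) y <- X$meta$label
  is_proxy <- y == ood_label()
  if (!any(is_proxy)) stop("no proxy class rows in training data")
  if (!any(!is_proxy)) stop("no in-distribution rows in training data")
  keep <- seq_along(y)
  if (match_size && sum(is_proxy) > sum(!is_proxy)) {
    set.seed(seed)
    keep <- sort(c(which(!is_proxy), sample(which(is_proxy), sum(!is_proxy))))
  }
  if (base == "fcn") {
    stopifnot(inherits(X, "window_set"))
    model <- fit_fcn(ws_subset(X, keep), cfg = fcn_cfg)
    return(new_detector("proxy_fcn", list(model = model)))
  }
  M <- if (is.matrix(X)) X else feature_values(X)
  M <- M[keep, , drop = FALSE]
  yk <- y[keep]
  if (base == "random_forest") {
    set.seed(seed)
    rf <- randomForest::randomForest(x = M, y = factor(yk), ntree = 100L)
    # out-of-bag OOD vote fractions, row-aligned with the (kept) training
    # rows: resubstitution scores of a forest are near zero and would yield a
    # degenerate threshold, so calibration uses these instead
    oob <- as.numeric(rf$votes[, ood_label()])
    oob[!is.finite(oob)] <- 0
    return(new_detector("proxy_rf", list(model = rf, oob_ood = oob,
                                         train_labels = yk)))
  }
  new_detector("proxy_patient_knn",
               list(support = M, support_is_proxy = yk == ood_label(),
                    k = as.integer(k)))
}

knn_mean_dist <- function(Q, S, k) {
  k <- min(k, nrow(S))
  D <- sqrt(pairwise_dist2(Q, S))
  apply(D, 1L, function(d) mean(sort(d, partial = k)[seq_len(k)]))
}

knn_proxy_fraction <- function(Q, S, is_proxy, k) {
  k <- min(k, nrow(S))
  D2 <- pairwise_dist2(Q, S)
  apply(D2, 1L, function(d) mean(is_proxy[order(d)[seq_len(k)]]))
}

#' Score windows for OOD-ness
#'
#' Higher scores mean more likely non-exercise. Pure function of the fitted
#' detector and the input.
#'
#' @param detector A fitted `ood_detector`.
#' @param newdata `feature_tbl`/matrix (distance- and forest-based kinds) or
#'   [window_set()] (FCN-based kinds).
#' @return Numeric score vector.
#' @export
ood_scores <- function(detector, newdata) {
  stopifnot(inherits(detector, "ood_detector"))
  kind <- detector$kind
  if (kind %in% c("softmax", "proxy_fcn")) {
    P <- predict_proba(detector$model, newdata)
    return(switch(kind,
      softmax = 1 - apply(P, 1L, max),
      proxy_fcn = as.numeric(P[, ood_label()])
    ))
  }
  M <- if (is.matrix(newdata)) newdata else feature_values(newdata)
  unname(switch(kind,
    kmeans = {
      D2 <- pairwise_dist2(M, detector$centers)
      sqrt(apply(D2, 1L, min))
    },
    patient_knn = knn_mean_dist(M, detector$support, detector$k),
    proxy_rf = {
      P <- predict(detector$model, M, type = "prob")
      as.numeric(P[, ood_label()])
    },
    proxy_patient_knn = knn_proxy_fraction(M, detector$support,
                                           detector$support_is_proxy, detector$k),
    stop("unknown detector kind ", kind)
  ))
}

#' Sensitivity-constrained threshold selection
#'
#' Given OOD scores of known-exercise calibration windows, returns the
#' smallest observed score `tau` such that the fraction of calibration scores
#' at or below `tau` meets the sensitivity target — the most specific
#' threshold that still guarantees the target sensitivity on the calibration
#' set (the rule "exercise iff score <= tau").
#'
#' @param scores_exercise OOD scores of calibration exercise windows.
#' @param sensitivity_target Minimum sensitivity in (0, 1]; default 0.90.
#' @return The threshold `tau`.
#' @examples
#' calibrate_threshold(c(0.1, 0.2, 0.3, 0.9), 0.75) # 0.3
#' calibrate_threshold(c(0.1, 0.2, 0.3, 0.9), 0.90) # 0.9
#' @export
calibrate_threshold <- function(scores_exercise, sensitivity_target = 0.90) {
  stopifnot(sensitivity_target > 0, sensitivity_target <= 1)
  if (length(scores_exercise) == 0L) stop("no calibration scores supplied")
  s <- sort(scores_exercise)
  s[ceiling(sensitivity_target * length(s))]
}

#' Calibrate a detector's threshold on exercise windows
#'
#' Computes the detector's scores on the supplied calibration exercise
#' windows (training split only — never the test subject's session) and
#' stores the sensitivity-constrained threshold. For patient-specific KNN
#' detectors calibrated on their own support set, pass
#' `loo = TRUE` to score each support row against the others
#' (leave-one-out), avoiding the zero-distance bias of scoring a row against
#' itself.
#'
#' @param detector A fitted `ood_detector`.
#' @param calib `feature_tbl`/matrix or [window_set()] of known-exercise
#'   windows (ignored when `loo = TRUE`).
#' @param sensitivity_target Minimum sensitivity (0.90).
#' @param loo Leave-one-out calibration on the detector's own support set
#'   (kinds `patient_knn` and `proxy_patient_knn` only).
#' @param oob Calibrate a `proxy_rf` detector on its out-of-bag OOD vote
#'   fractions over the exercise training rows (resubstitution scores of a
#'   forest are degenerate near zero); ignores `calib`.
#' @return The detector with `threshold` and `calibration` (achieved
#'   sensitivity, score count) filled in.
#' @export
calibrate_detector <- function(detector, calib = NULL, sensitivity_target = 0.90,
                               loo = FALSE, oob = FALSE) {
  scores <- if (loo) {
    loo_support_scores(detector)
  } else if (oob) {
    if (detector$kind != "proxy_rf") stop("oob calibration applies to proxy_rf")
    detector$oob_ood[detector$train_labels != ood_label()]
  } else {
    ood_scores(detector, calib)
  }
  tau <- calibrate_threshold(scores, sensitivity_target)
  detector$threshold <- tau
  detector$calibration <- list(
    sensitivity_target = sensitivity_target,
    achieved_sensitivity = mean(scores <= tau),
    n_scores = length(scores), loo = loo
  )
  detector
}

loo_support_scores <- function(detector) {
  if (!detector$kind %in% c("patient_knn", "proxy_patient_knn")) {
    stop("leave-one-out calibration applies to patient-specific KNN detectors")
  }
  S <- detector$support
  if (detector$kind == "proxy_patient_knn") {
    ex <- which(!detector$support_is_proxy)
    vapply(ex, function(i) {
      knn_proxy_fraction(S[i, , drop = FALSE], S[-i, , drop = FALSE],
                         detector$support_is_proxy[-i], detector$k)
    }, numeric(1L))
  } else {
    vapply(seq_len(nrow(S)), function(i) {
      knn_mean_dist(S[i, , drop = FALSE], S[-i, , drop = FALSE], detector$k)
    }, numeric(1L))
  }
}

#' Apply a calibrated detector
#'
#' @param detector A calibrated `ood_detector`.
#' @param newdata Features or windows, as for [ood_scores()].
#' @return A tibble with `score` and logical `keep` (`score <= threshold`,
#'   i.e. predicted exercise).
#' @export
detect <- function(detector, newdata) {
  if (is.null(detector$threshold)) {
    stop("state error: detector is uncalibrated; run calibrate_detector() first")
  }
  score <- ood_scores(detector, newdata)
  tibble::tibble(score = score, keep = score <= detector$threshold)
}

#' @export
glance.ood_detector <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    threshold = if (is.null(x$threshold)) NA_real_ else x$threshold,
    achieved_sensitivity = if (is.null(x$calibration)) NA_real_
      else x$calibration$achieved_sensitivity,
    n_calibration = if (is.null(x$calibration)) NA_integer_
      else x$calibration$n_scores
  )
}
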