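#' Derive each record's exercise class from its label track
#'
#' A clinic record's class is the exercise with the greatest total labelled
#' duration in its sidecar. Used when a manifest does not already carry a
#' `class` column.
#'
#' @param manifest A manifest tibble with `label_file` paths.
#' @return The manifest with a `class` column (`NA` for unlabelled records).
#' @export
manifest_record_classes <- function(manifest) {
  if ("class" %in% names(manifest)) return(manifest)
  manifest$class <- purrr::map_chr(manifest$label_file, function(lf) {
    if (is.na(lf)) return(NA_character_)
    track <- read_label_track(lf)
    ex <- track[track$class != ood_label(), , drop = FALSE]
    if (nrow(ex) == 0L) return(NA_character_)
    dur <- tapply(ex$t_end - ex$t_start, ex$class, sum)
    names(dur)[which.max(dur)]
  })
  manifest
}

#' Build a subject-wise session-aware cross-validation plan
#'
#' Subjects are shuffled by seed and partitioned into `n_folds` folds as
#' evenly as possible. For each subject, the test set is their most recent
#' supervised session; the patient-specific support for each class is drawn
#' from the most recent *earlier* session containing that class (usually the
#' second-to-last session). Test records whose class never appears in any of
#' the subject's earlier sessions are excluded — identically for every
#' method, so all methods see the same test set. Subjects with fewer than two
#' supervised sessions cannot provide support and are flagged.
#'
#' @param manifest Manifest tibble (clinic records are used; a `class` column
#'   is derived from the label sidecars when absent).
#' @param n_folds Number of folds (5).
#' @param seed Shuffle seed.
#' @return A `cv_plan` with tibbles `folds` (subject, fold), `test_records`
#'   (with `excluded` and `reason`), `support_records` and `train_records`.
#' @export
make_cv_plan <- function(manifest, n_folds = 5L, seed = 0L) {
  clinic <- manifest[manifest$setting == "clinic", , drop = FALSE]
  clinic <- manifest_record_classes(clinic)
  subjects <- sort(unique(clinic$subject_id))
  if (length(subjects) < n_folds) {
    stop("need at least ", n_folds, " subjects for ", n_folds, "-fold CV")
  }
  set.seed(seed)
  shuffled <- sample(subjects)
  folds <- tibble::tibble(subject_id = shuffled,
                          fold = rep(seq_len(n_folds), length.out = length(shuffled)))

  per_subj <- dplyr::group_by(clinic, .data$subject_id)
  sessions <- dplyr::summarise(per_subj,
    test_session = max(.data$session_index),
    n_sessions = dplyr::n_distinct(.data$session_index), .groups = "drop")
  sessions$support_available <- sessions$n_sessions >= 2L

  test_records <- dplyr::inner_join(clinic, sessions,
                                    by = "subject_id")
  test_records <- test_records[test_records$session_index == test_records$test_session, ,
                               drop = FALSE]
  # exclusion: test record class must have earlier-session data for the subject
  hist_classes <- dplyr::distinct(
    dplyr::inner_join(clinic, sessions[, c("subject_id", "test_session")],
                      by = "subject_id") |>
      dplyr::filter(.data$session_index < .data$test_session),
    .data$subject_id, .data$class, .data$session_index
  )
  has_support <- dplyr::distinct(hist_classes, .data$subject_id, .data$class)
  has_support$has_support <- TRUE
  test_records <- dplyr::left_join(test_records, has_support,
                                   by = c("subject_id", "class"))
  test_records$excluded <- is.na(test_records$has_support)
  test_records$reason <- ifelse(test_records$excluded,
                                "no earlier-session data of this class", NA_character_)
  test_records <- dplyr::left_join(test_records, folds, by = "subject_id")

  # support: per (subject, class), records of the most recent earlier session
  support_sessions <- dplyr::summarise(
    dplyr::group_by(hist_classes, .data$subject_id, .data$class),
    support_session = max(.data$session_index), .groups = "drop")
  support_records <- dplyr::inner_join(
    clinic, support_sessions,
    by = c("subject_id", "class")
  )
  support_records <- support_records[support_records$session_index ==
                                       support_records$support_session, , drop = FALSE]

  train_records <- dplyr::left_join(clinic, folds, by = "subject_id")
  cols <- c("record_id", "subject_id", "session_index", "class", "fold")
  structure(list(
    n_folds = as.integer(n_folds), seed = as.integer(seed),
    folds = folds, sessions = sessions,
    test_records = test_records[, c(cols, "excluded", "reason")],
    support_records = support_records[, c("record_id", "subject_id",
                                          "session_index", "class")],
    train_records = train_records[, cols]
  ), class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d folds, %d subjects, %d test records (%d excluded)\n",
              x$n_folds, nrow(x$folds), nrow(x$test_records),
              sum(x$test_records$excluded)))
  invisible(x)
}

#' Training records of one fold
#'
#' All clinic records of subjects outside the test fold. The test subjects'
#' records — including their earlier sessions — never enter training.
#'
#' @param plan A `cv_plan`.
#' @param fold Fold number.
#' @return Tibble of training records.
#' @export
cv_train_records <- function(plan, fold) {
  plan$train_records[plan$train_records$fold != fold, , drop = FALSE]
}

#' @rdname cv_train_records
#' @export
cv_test_records <- function(plan, fold) {
  tr <- plan$test_records
  tr[tr$fold == fold & !tr$excluded, , drop = FALSE]
}

#' Rank-based AUROC
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one-half (the Mann-Whitney statistic). Scores must be oriented so
#' that higher means more positive-class-like; for OOD scores (higher =
#' non-exercise) pass their negation with exercise as positive.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param positive Logical vector: TRUE for positive-class elements.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  positive <- as.logical(positive)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined-metric error: AUROC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-based binary metrics
#'
#' @param pred,truth Logical vectors (TRUE = exercise) of equal length.
#' @return One-row tibble: `accuracy`, `sensitivity` (TP/(TP+FN)),
#'   `specificity` (TN/(TN+FP)), `precision`, `f1` (0 when precision and
#'   recall are both 0; `NA` where undefined because a class is absent).
#' @export
binary_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0L) tp / (tp + fp) else 0
  f1 <- if (tp + fn > 0L) {
    if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  } else NA_real_
  tibble::tibble(accuracy = (tp + tn) / length(pred), sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1)
}

#' Per-record detection metrics
#'
#' Evaluates a detector's window scores and keep mask against a record's
#' ground-truth exercise mask. Records containing no true exercise windows
#' contribute specificity only (their sensitivity, F1 and AUROC are `NA`),
#' matching the convention of excluding exercise-free records from
#' sensitivity/F1 summaries.
#'
#' @param scores Window OOD scores (higher = non-exercise).
#' @param keep Logical: windows kept as exercise.
#' @param truth Logical: windows truly exercise.
#' @param record_id Identifier carried through to the output.
#' @return One-row tibble of `auroc`, `f1`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
evaluate_record <- function(scores, keep, truth, record_id = NA_character_) {
  truth <- as.logical(truth)
  bm <- binary_metrics(keep, truth)
  au <- if (any(truth) && any(!truth)) auroc(-scores, truth) else NA_real_
  tibble::tibble(record_id = record_id, n_windows = length(truth),
                 n_exercise = sum(truth), auroc = au, f1 = bm$f1,
                 sensitivity = bm$sensitivity, specificity = bm$specificity,
                 accuracy = bm$accuracy)
}

#' Run the two-stage pipeline on one batch of windows
#'
#' Stage 1 removes windows the calibrated detector scores as
#' out-of-distribution; stage 2 labels the retained windows with the
#' classifier. Removed windows are labelled [ood_label()].
#'
#' @param detector Calibrated `ood_detector`.
#' @param det_data Detector input ([ood_scores()] conventions).
#' @param classify_fn Function mapping a subset of `clf_data` to labels, e.g.
#'   `function(d) predict(rf, d)`.
#' @param clf_data Classifier input, subsettable by window index (defaults to
#'   `det_data`).
#' @return Tibble with `score`, `keep`, `pred`.
#' @export
run_two_stage <- function(detector, det_data, classify_fn, clf_data = det_data) {
  d <- detect(detector, det_data)
  pred <- rep(ood_label(), nrow(d))
  if (any(d$keep)) {
    sub <- if (inherits(clf_data, "window_set")) ws_subset(clf_data, which(d$keep))
           else clf_data[which(d$keep), , drop = FALSE]
    pred[d$keep] <- classify_fn(sub)
  }
  dplyr::mutate(d, pred = pred)
}

#' Aggregate per-fold metrics into means and standard errors
#'
#' @param fold_metrics Tibble with a `fold` column and one or more numeric
#'   metric columns (or a long tibble with `metric`/`value`).
#' @return Long tibble: `metric`, `mean`, `se` (`sd` of fold values over
#'   `sqrt(n_folds)`), `n_folds`.
#' @export
aggregate_cv <- function(fold_metrics) {
  if (!all(c("metric", "value") %in% names(fold_metrics))) {
    fold_metrics <- tidyr::pivot_longer(fold_metrics, -dplyr::any_of("fold"),
                                        names_to = "metric", values_to = "value")
  }
  dplyr::summarise(
    dplyr::group_by(fold_metrics, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    n_folds = sum(!is.na(.data$value)),
    .groups = "drop"
  )
}

#' Verify the fine-to-coarse accuracy guarantee
#'
#' A correct exercise-level prediction stays correct after any grouping, so
#' coarsened accuracy can never fall below exercise-level accuracy on the
#' same windows. Called on every evaluation run; stops on violation.
#'
#' @param pred,truth Exercise-level predicted and true labels.
#' @param level Grouping level to check.
#' @return Invisibly, a tibble with both accuracies.
#' @export
assert_coarsening <- function(pred, truth, level) {
  acc_fine <- mean(pred == truth)
  acc_coarse <- mean(apply_grouping(pred, level) == apply_grouping(truth, level))
  if (acc_coarse < acc_fine - 1e-12) {
    stop("coarsening violation: ", level, " accuracy ", acc_coarse,
         " < exercise accuracy ", acc_fine)
  }
  invisible(tibble::tibble(level = level, acc_exercise = acc_fine,
                           acc_grouped = acc_coarse))
}
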