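test_that("AUROC handles separation, mixtures and ties", {
  expect_equal(auroc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auroc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auroc(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "undefined-metric")
})

test_that("AUROC equals the brute-force all-pairs statistic", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    sc <- round(rnorm(n), 1)               # ties likely
    pos <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(auroc(sc, pos), auroc_brute(sc, pos), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly increasing transforms", {
  set.seed(22)
  sc <- rnorm(50)
  pos <- rep(c(TRUE, FALSE), 25)
  a <- auroc(sc, pos)
  expect_equal(auroc(exp(sc), pos), a, tolerance = 1e-12)
  expect_equal(auroc(sc^3 + 2 * sc, pos), a, tolerance = 1e-12)
})

test_that("binary metrics reproduce confusion-table arithmetic", {
  # TP=3 FP=1 FN=1 TN=5
  pred <- c(rep(TRUE, 4), rep(FALSE, 6))
  truth <- c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5))
  m <- binary_metrics(pred, truth)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)

  perfect <- binary_metrics(truth, truth)
  expect_true(all(unlist(perfect[, c("accuracy", "sensitivity", "specificity",
                                     "f1")]) == 1))

  none <- binary_metrics(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$f1, 0)

  expect_error(binary_metrics(c(TRUE, FALSE), TRUE), "lengths differ")
})

test_that("exercise-free records contribute specificity only", {
  r <- evaluate_record(scores = c(1, 2, 3, 4), keep = c(FALSE, FALSE, FALSE, FALSE),
                       truth = rep(FALSE, 4), "r0")
  expect_equal(r$specificity, 1)
  expect_true(is.na(r$f1) && is.na(r$sensitivity) && is.na(r$auroc))

  r2 <- evaluate_record(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                        rep(FALSE, 4), "r0")
  expect_equal(r2$specificity, 0.5)

  r3 <- evaluate_record(c(0, 0, 5, 5), c(TRUE, TRUE, FALSE, FALSE),
                        c(TRUE, TRUE, FALSE, FALSE), "r1")
  expect_true(all(unlist(r3[, c("auroc", "f1", "sensitivity",
                                "specificity")]) == 1))
})

test_that("fold aggregation reports mean and standard error", {
  fm <- tibble::tibble(fold = 1:2, auroc = c(0.8, 0.9))
  agg <- aggregate_cv(fm)
  expect_equal(agg$mean, 0.85)
  expect_equal(agg$se, sd(c(0.8, 0.9)) / sqrt(2))
  agg2 <- aggregate_cv(tibble::tibble(fold = 1:3, f1 = rep(0.7, 3)))
  expect_equal(agg2$se, 0)
})

test_that("the CV plan partitions subjects evenly and deterministically", {
  man <- random_manifest(1)
  # widen to exactly 10 subjects for the fold-size check
  man10 <- dplyr::bind_rows(lapply(1:10, function(s) {
    m <- random_manifest(s)
    m$subject_id <- sprintf("P%02d", s)
    m$record_id <- paste0(m$record_id, "_P", s)
    m
  }))
  plan <- make_cv_plan(man10, n_folds = 5, seed = 3)
  expect_equal(as.integer(table(plan$folds$fold)), rep(2L, 5))
  expect_equal(dplyr::n_distinct(plan$folds$subject_id), 10L)
  plan2 <- make_cv_plan(man10, n_folds = 5, seed = 3)
  expect_identical(plan$folds, plan2$folds)
  expect_identical(plan$test_records, plan2$test_records)
  expect_error(make_cv_plan(man10, n_folds = 11), "at least 11")
})

test_that("the support-exclusion rule removes exactly the unsupported classes", {
  man <- tibble::tibble(
    record_id = c("a1", "a2", "b1", "b2"),
    subject_id = c("S1", "S1", "S1", "S1"),
    session_index = c(1L, 1L, 2L, 2L),
    setting = "clinic", record_file = NA_character_, label_file = NA_character_,
    class = c("Push up", "Push up", "Push up", "Resisted row"))
  man <- dplyr::bind_rows(man, dplyr::mutate(
    man, subject_id = "S2", record_id = paste0(record_id, "x")))
  plan <- make_cv_plan(man, n_folds = 2, seed = 1)
  tr <- plan$test_records
  # last-session Push up has session-1 support; Resisted row has none
  expect_true(all(tr$excluded[tr$class == "Resisted row"]))
  expect_false(any(tr$excluded[tr$class == "Push up"]))
  expect_match(tr$reason[tr$excluded][1], "no earlier-session")
  # support comes from the most recent earlier session containing the class
  expect_true(all(plan$support_records$session_index == 1L))
})

test_that("no training record ever belongs to a test-fold subject", {
  for (seed in 1:10) {
    man <- random_manifest(seed)
    plan <- make_cv_plan(man, n_folds = 3, seed = seed)
    for (f in 1:3) {
      test_subjects <- plan$folds$subject_id[plan$folds$fold == f]
      expect_length(intersect(cv_train_records(plan, f)$subject_id,
                              test_subjects), 0)
      expect_true(all(cv_test_records(plan, f)$subject_id %in% test_subjects))
    }
  }
})

test_that("two-stage output labels removed windows as OOD", {
  S <- rbind(c(0, 0), c(0.2, 0), c(0, 0.2))
  det <- calibrate_detector(fit_patient_knn_detector(S, k = 3), S, 0.9)
  Q <- rbind(c(0.1, 0), c(50, 50))
  out <- run_two_stage(det, Q, function(d) rep("Push up", nrow(d)), Q)
  expect_equal(out$pred, c("Push up", ood_label()))

  det$threshold <- -Inf
  out2 <- run_two_stage(det, Q, function(d) stop("never called"), Q)
  expect_true(all(out2$pred == ood_label()))
})
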