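test_that("kmeans detector scores are distances to the nearest centroid", {
  b <- blob_features(40, rbind(A = c(0, 0), B = c(5, 5)), seed = 2)
  det <- fit_kmeans_detector(b$X, n_clusters = 2, seed = 1)
  # recoverable centroids
  ctrs <- det$centers[order(det$centers[, 1]), ]
  expect_lt(max(abs(ctrs[1, ] - c(0, 0))), 0.1)
  expect_lt(max(abs(ctrs[2, ] - c(5, 5))), 0.1)
  # a point equal to a centroid scores 0
  expect_equal(ood_scores(det, det$centers[1, , drop = FALSE]), 0,
               tolerance = 1e-12)
  # brute-force oracle on random queries
  set.seed(3)
  Q <- matrix(rnorm(200, sd = 3), 100, 2)
  got <- ood_scores(det, Q)
  want <- apply(Q, 1, kmeans_score_brute, centers = det$centers)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("kmeans detector validates its cluster count", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_kmeans_detector(X, 0), "parameter error")
  expect_error(fit_kmeans_detector(X, 11), "parameter error")
})

test_that("patient KNN scores are mean distances to the k nearest rows", {
  S <- rbind(c(0, 0), c(1, 0), c(2, 0), c(50, 50))
  det <- fit_patient_knn_detector(S, k = 3)
  # query on a support row: distances 0, 1, 2 -> mean 1
  expect_equal(ood_scores(det, S[1, , drop = FALSE]), 1)
  # support of exactly k rows: mean of all distances
  det3 <- fit_patient_knn_detector(S[1:3, ], k = 3)
  q <- matrix(c(0, 1), 1)
  expect_equal(ood_scores(det3, q),
               mean(sqrt(rowSums(sweep(S[1:3, ], 2, c(0, 1))^2))))
  # brute-force oracle
  set.seed(4)
  S2 <- matrix(rnorm(60), 20, 3)
  Q <- matrix(rnorm(300), 100, 3)
  det2 <- fit_patient_knn_detector(S2, k = 3)
  expect_equal(ood_scores(det2, Q),
               apply(Q, 1, knn_mean_dist_brute, S = S2, k = 3),
               tolerance = 1e-10)
})

test_that("small or empty support sets warn or fail", {
  expect_warning(fit_patient_knn_detector(matrix(0, 2, 2), k = 3), "k = 3")
  expect_error(fit_patient_knn_detector(matrix(0, 0, 2)), "empty support")
})

test_that("softmax detector scores one minus the top probability", {
  ws <- toy_window_set(40L, L = 24L, seed = 12)
  m <- fit_fcn(ws, cfg = fcn_config(epochs = 2L, batch_size = 16L, seed = 1L))
  det <- fit_softmax_detector(m)
  P <- predict_proba(m, ws)
  expect_equal(ood_scores(det, ws), 1 - apply(P, 1, max), tolerance = 1e-12)
  # the score functional itself at reference probability rows
  rows <- rbind(c(1, 0, 0), c(1, 1, 1) / 3, c(0.5, 0.3, 0.2))
  expect_equal(1 - apply(rows, 1, max), c(0, 1 - 1 / 3, 0.5))
})

test_that("proxy KNN detector scores the proxy fraction of neighbours", {
  S <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(9, 9), c(9.1, 9), c(9, 9.1))
  y <- c("Push up", "Push up", "Push up", ood_label(), ood_label(), ood_label())
  det <- fit_proxy_detector(S, y, base = "patient_knn", k = 3)
  expect_equal(ood_scores(det, matrix(c(0, 0), 1)), 0)
  expect_equal(ood_scores(det, matrix(c(9, 9), 1)), 1)   # all 3 NN proxy
})

test_that("proxy random forest separates a separable construction", {
  b <- blob_features(60, rbind(A = c(0, 0), B = c(4, 0), OOD = c(2, 6)),
                     seed = 6)
  y <- ifelse(b$y == "OOD", ood_label(), b$y)
  det <- fit_proxy_detector(b$X, y, base = "random_forest", seed = 1)
  sc <- ood_scores(det, b$X)
  expect_true(all(sc[y != ood_label()] < 0.2))   # resubstitution ~ 0
  expect_true(all(sc[y == ood_label()] > 0.8))
  # far-away exercise query scores low, proxy-side query scores high
  expect_lt(ood_scores(det, matrix(c(0, 0), 1)), 0.5)
  expect_gt(ood_scores(det, matrix(c(2, 6), 1)), 0.5)
})

test_that("proxy detectors demand a proxy class and size-match it", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_proxy_detector(X, rep("A", 20), base = "random_forest"),
               "no proxy")
  y <- c(rep("A", 5), rep(ood_label(), 15))
  det <- fit_proxy_detector(X, y, base = "patient_knn", match_size = TRUE,
                            seed = 1)
  expect_equal(sum(det$support_is_proxy), 5L)  # matched down to n_id
})

test_that("threshold calibration picks the smallest sufficient score", {
  s <- c(0.1, 0.2, 0.3, 0.9)
  expect_equal(calibrate_threshold(s, 0.75), 0.3)
  expect_equal(calibrate_threshold(s, 0.90), 0.9)
  expect_equal(calibrate_threshold(rep(0.5, 10), 0.4), 0.5)
  expect_error(calibrate_threshold(numeric(0)), "no calibration scores")

  # enumeration oracle + guarantee, over random score sets and targets
  set.seed(11)
  for (i in 1:50) {
    sc <- round(rexp(sample(3:40, 1)), 2)   # ties likely
    target <- runif(1, 0.05, 1)
    tau <- calibrate_threshold(sc, target)
    expect_equal(tau, calibrate_brute(sc, target))
    expect_gte(mean(sc <= tau), target)
    smaller <- sc[sc < tau]
    if (length(smaller) > 0) {
      expect_lt(mean(sc <= max(smaller)), target)
    }
  }
})

test_that("calibrated detectors keep exactly the sub-threshold windows", {
  S <- matrix(rnorm(30), 15, 2)
  det <- fit_patient_knn_detector(S, k = 3)
  expect_error(detect(det, S), "uncalibrated")
  det <- calibrate_detector(det, S, 0.9)
  out <- detect(det, S)
  expect_identical(out$keep, out$score <= det$threshold)

  det$threshold <- Inf
  expect_true(all(detect(det, S)$keep))
  det$threshold <- -Inf
  expect_false(any(detect(det, S)$keep))

  # monotonicity: kept count never decreases as tau grows
  sc <- ood_scores(det, S)
  kept <- vapply(sort(c(sc, 0, 10)), function(tau) sum(sc <= tau), 1L)
  expect_true(all(diff(kept) >= 0))
})

test_that("leave-one-out calibration on the support avoids zero-distance bias", {
  set.seed(20)
  S <- matrix(rnorm(40), 20, 2)
  det <- fit_patient_knn_detector(S, k = 3)
  det <- calibrate_detector(det, sensitivity_target = 0.9, loo = TRUE)
  loo <- rehabsense:::loo_support_scores(det)
  expect_true(all(loo > 0))                      # no self-match zeros
  expect_gte(mean(loo <= det$threshold), 0.9)
  expect_gte(det$calibration$achieved_sensitivity, 0.9)
})

test_that("detector scores are pure functions of their input", {
  set.seed(8)
  S <- matrix(rnorm(40), 20, 2)
  Q <- matrix(rnorm(20), 10, 2)
  for (det in list(fit_patient_knn_detector(S, k = 3),
                   fit_kmeans_detector(S, 3, seed = 1))) {
    s1 <- ood_scores(det, Q)
    s2 <- ood_scores(det, Q[c(1:10, 1), ])
    expect_equal(s2[11], s1[1])
    expect_equal(s2[1:10], s1)
  }
})
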