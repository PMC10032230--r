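test_that("class templates are deterministic and collapse when separation is 0", {
  cls <- default_classes()
  t1 <- make_class_templates(cls, sep = 1, seed = 5)
  t2 <- make_class_templates(cls, sep = 1, seed = 5)
  expect_identical(t1, t2)

  t0 <- make_class_templates(cls, sep = 0, seed = 5)
  for (i in seq_along(t0)) {
    expect_equal(t0[[i]]$orientation, c(0, 0, 1))
    expect_identical(t0[[i]]$amp, t0[[1]]$amp)
    expect_identical(t0[[i]]$phase, t0[[1]]$phase)
  }
  expect_error(make_class_templates(c("Push up", "Push up")), "duplicate")
  expect_error(make_class_templates(c("Push up", "Sit up")), "Sit up")
})

test_that("templates are more similar within a simple-motion group than between", {
  cls <- default_classes()
  groups <- taxonomy()$simple_motion[match(cls, taxonomy()$exercise)]
  cos_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- between <- c()
  for (seed in 1:60) {
    tpl <- make_class_templates(cls, sep = 1, seed = seed)
    for (i in 1:(length(cls) - 1)) for (j in (i + 1):length(cls)) {
      s <- cos_sim(as.numeric(tpl[[i]]$amp), as.numeric(tpl[[j]]$amp))
      if (groups[i] == groups[j]) within <- c(within, s) else
        between <- c(between, s)
    }
  }
  expect_gt(mean(within), mean(between))
})

test_that("repetition periods match the right-skewed parameterization", {
  set.seed(1)
  p <- draw_periods(10000)
  expect_gt(mean(p), 3.7)
  expect_lt(mean(p), 3.9)
  expect_gt(sd(p), 2.0)
  expect_lt(sd(p), 2.6)
  m <- mean(p)
  skew <- mean((p - m)^3) / (mean((p - m)^2))^1.5
  expect_gt(skew, 0)
  expect_true(all(p > 0))
  expect_equal(draw_periods(5, sd = 0), rep(3.8, 5))
})

test_that("a motionless noiseless bout is pure gravity", {
  cfg <- cohort_config(noise_sd = 0, amp_accel = 0, amp_gyro = 0,
                       irregular = FALSE)
  tpl <- make_class_templates(cfg$classes, sep = 1, seed = 1)[[1]]
  bout <- generate_bout(tpl, n_reps = 3, cfg, seed = 2)
  norms <- sqrt(rowSums(bout$signal[, 1:3]^2))
  expect_equal(norms, rep(9.81, length(norms)), tolerance = 1e-9)
  expect_true(all(bout$signal[, 4:6] == 0))
  expect_equal(bout$duration, sum(bout$periods))
})

test_that("ADL segments are deterministic and scale with intensity", {
  cfg <- cohort_config(irregular = FALSE)
  a1 <- generate_adl_segment(1, 10, cfg, seed = 3)
  a2 <- generate_adl_segment(1, 10, cfg, seed = 3)
  expect_identical(a1$signal, a2$signal)

  still <- generate_adl_segment(0, 10, cohort_config(noise_sd = 0,
                                                     irregular = FALSE),
                                seed = 4)
  expect_equal(sqrt(rowSums(still$signal[, 1:3]^2)),
               rep(9.81, nrow(still$signal)), tolerance = 1e-9)
  expect_true(all(still$signal[, 4:6] == 0))

  # gyro RMS grows with intensity (averaged over seeds)
  rms_at <- function(int) {
    mean(vapply(1:20, function(s) {
      sqrt(mean(generate_adl_segment(int, 8, cfg, seed = s)$signal[, 4:6]^2))
    }, 1))
  }
  grid <- c(0.2, 0.8, 1.6)
  vals <- vapply(grid, rms_at, 1)
  expect_true(all(diff(vals) > 0))
})

test_that("cohorts are fully deterministic under their seed", {
  cfg <- cohort_config(n_subjects = 3, n_sessions = 2, home_duration = 60,
                       n_proxy_subjects = 1, proxy_duration = 60, seed = 9)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  rid <- c1$manifest$record_id[1]
  expect_identical(c1$records[[rid]]$record$ax, c2$records[[rid]]$record$ax)
  expect_identical(as.data.frame(c1$records[[rid]]$track),
                   as.data.frame(c2$records[[rid]]$track))
  pid <- c1$proxy_manifest$record_id[1]
  expect_identical(c1$proxy_records[[pid]]$record$gz,
                   c2$proxy_records[[pid]]$record$gz)
})

test_that("the cohort layout matches its configuration", {
  co <- small_cohort()
  cfg <- co$config
  man <- co$manifest
  clinic <- man[man$setting == "clinic", ]
  expect_equal(dplyr::n_distinct(man$subject_id), cfg$n_subjects)
  expect_true(all(clinic$session_index %in% seq_len(cfg$n_sessions)))
  # one clinic record per performed exercise per session, so each
  # subject-session has between 1 and classes_per_subject records
  per_sess <- dplyr::count(clinic, .data$subject_id, .data$session_index)
  expect_true(all(per_sess$n >= 1 & per_sess$n <= cfg$classes_per_subject))
  expect_equal(sum(man$setting == "home"),
               cfg$n_subjects * cfg$n_home_records)
  expect_equal(nrow(co$proxy_manifest), cfg$n_proxy_subjects)
  # proxy subjects are disjoint from cohort subjects and all non-exercise
  expect_length(intersect(co$proxy_manifest$subject_id, man$subject_id), 0)
  expect_true(all(vapply(co$proxy_records,
                         function(r) nrow(r$track) == 0L, TRUE)))
})

test_that("home-record masks account exactly for the scheduled bouts", {
  co <- small_cohort()
  hid <- co$manifest$record_id[co$manifest$setting == "home"][1]
  entry <- co$records[[hid]]
  mask <- label_mask(entry$record$t, entry$track)
  # per-sample mask duration of exercise ~ total labelled interval length
  dt <- 1 / co$config$rate
  expect_equal(sum(mask != ood_label()) * dt,
               sum(entry$track$t_end - entry$track$t_start),
               tolerance = 0.1 * max(1, nrow(entry$track)))
  # every labelled class was prescribed to that subject
  subj <- co$manifest$subject_id[co$manifest$record_id == hid]
  expect_true(all(entry$track$class %in% co$prescriptions[[subj]]))
  # long near-static stretch exists: a >50 s gap between exercise intervals
  gaps <- diff(c(0, sort(c(entry$track$t_start, entry$track$t_end)),
                 max(entry$record$t)))
  expect_true(max(gaps) > 30)
})

test_that("irregular timestamps jitter around the 50 Hz grid but stay ordered", {
  co <- small_cohort()
  rec <- co$records[[co$manifest$record_id[1]]]$record
  d <- diff(rec$t)
  expect_true(all(d > 0))
  expect_gt(sd(d), 0)                 # genuinely irregular
  expect_lt(max(abs(d - 0.02)), 0.009)
})

# ---- behavioural controls linking the generator to the pipeline ----------

# full prescriptions so class coverage does not cap accuracy
prop_cohort <- function(sep, subject_sd, seed) {
  simulate_cohort(cohort_config(
    n_subjects = 5L, n_sessions = 2L, classes_per_subject = 8L,
    perform_prob = 1, reps_range = c(3L, 5L), sep = sep,
    subject_sd = subject_sd, n_home_records = 0L, n_proxy_subjects = 1L,
    proxy_duration = 80, seed = seed))
}

split_features <- function(co) {
  pre <- preprocess_cohort(co)
  F <- extract_features(pre$clinic)
  meta <- pre$clinic$meta
  test_subj <- sort(unique(meta$subject_id))[1:2]
  is_test <- meta$subject_id %in% test_subj & meta$session_index == 2L
  is_train <- !meta$subject_id %in% test_subj
  sc <- fit_scaler(F, which(is_train))
  list(Z = feature_values(apply_scaler(F, sc)), meta = meta,
       train = which(is_train), test = which(is_test),
       proxy = feature_values(apply_scaler(extract_features(pre$proxy), sc)))
}

test_that("classification gets easier as class separation grows", {
  # separation scales between-class template deviations relative to the
  # shared motion backbone; exercise-vs-ADL contrast is governed mostly by
  # the backbone, so the detectors are checked at the grid endpoints while
  # classification accuracy must be monotone across the grid
  grid <- c(0.15, 0.6, 1.5)
  acc <- auc_km <- auc_knn <- matrix(0, 3, length(grid))
  for (si in 1:3) {
    for (gi in seq_along(grid)) {
      co <- prop_cohort(sep = grid[gi], subject_sd = 0.2, seed = 200 + si)
      sp <- split_features(co)
      y <- apply_grouping(sp$meta$label, "simple_motion")
      rf <- fit_random_forest(sp$Z[sp$train, ], y[sp$train], seed = 1)
      acc[si, gi] <- mean(predict(rf, sp$Z[sp$test, ]) == y[sp$test])
      km <- fit_kmeans_detector(sp$Z[sp$train, ],
                                dplyr::n_distinct(y[sp$train]), seed = 1)
      s <- c(ood_scores(km, sp$Z[sp$test, ]), ood_scores(km, sp$proxy))
      pos <- c(rep(TRUE, length(sp$test)), rep(FALSE, nrow(sp$proxy)))
      auc_km[si, gi] <- auroc(-s, pos)
      sup <- sp$train[1:60]
      knn <- fit_patient_knn_detector(sp$Z[sup, ], k = 3)
      s2 <- c(ood_scores(knn, sp$Z[sp$test, ]), ood_scores(knn, sp$proxy))
      auc_knn[si, gi] <- auroc(-s2, pos)
    }
  }
  expect_true(all(diff(colMeans(acc)) >= -1e-9))
  m_km <- colMeans(auc_km)
  m_knn <- colMeans(auc_knn)
  expect_gte(m_km[length(grid)], m_km[1])
  # detection quality is carried by the motion backbone, hence stays far
  # above chance at every separation rather than tracking the knob
  expect_true(all(m_km >= 0.75))
  expect_true(all(m_knn >= 0.75))
})

test_that("high subject variability favours the patient-specific classifier", {
  co <- simulate_cohort(cohort_config(
    n_subjects = 5L, n_sessions = 3L, classes_per_subject = 4L,
    reps_range = c(3L, 5L), sep = 0.35, subject_sd = 0.9,
    n_home_records = 0L, n_proxy_subjects = 1L, proxy_duration = 60,
    seed = 77))
  pre <- preprocess_cohort(co)
  F <- extract_features(pre$clinic)
  meta <- pre$clinic$meta
  plan <- make_cv_plan(co$manifest, n_folds = 2L, seed = 1)
  accs <- list(knn = c(), rf = c())
  for (f in 1:2) {
    tr <- which(meta$record_id %in% cv_train_records(plan, f)$record_id)
    te_rec <- cv_test_records(plan, f)
    te <- which(meta$record_id %in% te_rec$record_id)
    if (length(te) == 0) next
    sc <- fit_scaler(F, tr)
    Z <- feature_values(apply_scaler(F, sc))
    y <- apply_grouping(meta$label, "simple_motion")
    rf <- fit_random_forest(Z[tr, ], y[tr], seed = 1)
    accs$rf <- c(accs$rf, predict(rf, Z[te, ]) == y[te])
    for (s in unique(te_rec$subject_id)) {
      sup_rec <- plan$support_records$record_id[
        plan$support_records$subject_id == s]
      sup <- which(meta$record_id %in% sup_rec)
      s_te <- te[meta$subject_id[te] == s]
      if (length(sup) == 0 || length(s_te) == 0) next
      pred <- patient_knn_classify(Z[sup, ], Z[s_te, ], y[sup], k = 3)
      accs$knn <- c(accs$knn, pred == y[s_te])
    }
  }
  expect_gt(mean(accs$knn), mean(accs$rf))
})
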