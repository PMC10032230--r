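uniform_record <- function(n, rate = 50, seed = 1) {
  set.seed(seed)
  df <- data.frame(t = (seq_len(n) - 1) / rate, ax = rnorm(n), ay = rnorm(n),
                   az = rnorm(n), gx = rnorm(n), gy = rnorm(n), gz = rnorm(n))
  imu_record(df, "u", "s", 1L, "clinic")
}

test_that("resampling already-uniform input is the identity", {
  rec <- uniform_record(200)
  out <- resample_uniform(rec, 50)
  expect_equal(as.matrix(out), as.matrix(rec), tolerance = 1e-9)
})

test_that("resampling interpolates linearly between samples", {
  df <- data.frame(t = c(0, 0.04), ax = c(0, 4), ay = c(1, 1), az = c(0, 0),
                   gx = c(0, 0), gy = c(2, 4), gz = c(0, 0))
  out <- resample_uniform(imu_record(df, "r", "s", 1L, "clinic"), 50)
  expect_equal(out$t, c(0, 0.02, 0.04))
  expect_equal(out$ax, c(0, 2, 4))
  expect_equal(out$gy, c(2, 3, 4))
})

test_that("jittered sampling of a sine reconstructs the analytic signal", {
  set.seed(7)
  n <- 500L
  t <- (seq_len(n) - 1) / 50
  t[2:(n - 1)] <- t[2:(n - 1)] + runif(n - 2, -0.004, 0.004)
  amp <- 2
  sig <- amp * sin(2 * pi * 1.2 * t)
  df <- data.frame(t = t, ax = sig, ay = sig, az = sig, gx = sig, gy = sig,
                   gz = sig)
  out <- resample_uniform(imu_record(df, "r", "s", 1L, "clinic"), 50)
  expect_lt(max(abs(out$ax - amp * sin(2 * pi * 1.2 * out$t))), 0.01 * amp)
})

test_that("too-short records refuse to resample", {
  df <- data.frame(t = c(0, 0.01), ax = 0:1, ay = 0:1, az = 0:1, gx = 0:1,
                   gy = 0:1, gz = 0:1)
  expect_error(resample_uniform(imu_record(df, "r", "s", 1L, "clinic"), 50),
               "empty-output")
})

test_that("window counts follow floor((N-L)/s)+1 and match brute force", {
  cfg500 <- preprocess_config()
  expect_equal(n_windows(segment_windows(uniform_record(500), cfg500)), 1L)
  expect_equal(n_windows(segment_windows(uniform_record(1000), cfg500)), 11L)
  expect_equal(n_windows(segment_windows(uniform_record(549), cfg500)), 1L)

  set.seed(3)
  for (i in 1:25) {
    L <- sample(10:60, 1)
    s <- sample(seq_len(L), 1)
    N <- L + sample(0:200, 1)
    cfg <- preprocess_config(target_rate = 10, window_seconds = L / 10,
                             step_samples = s)
    ws <- segment_windows(uniform_record(N, rate = 10, seed = i), cfg)
    expect_equal(n_windows(ws), count_windows_brute(N, L, s))
    expect_equal(n_windows(ws), floor((N - L) / s) + 1L)
  }
})

test_that("short records yield an empty window set with a warning", {
  expect_warning(ws <- segment_windows(uniform_record(499)), "shorter")
  expect_equal(n_windows(ws), 0L)
})

test_that("each window equals the corresponding slice of the record", {
  rec <- uniform_record(700, seed = 11)
  ws <- segment_windows(rec, preprocess_config())
  X <- as.matrix(rec[, c("ax", "ay", "az", "gx", "gy", "gz")])
  for (i in seq_len(n_windows(ws))) {
    off <- round(ws$meta$start_time[i] * 50)
    expect_equal(ws$windows[i, , ], unname(X[off + 1:500, ]))
  }
})

test_that("window labels follow the strict-majority rule with ties to OOD", {
  cfg <- preprocess_config(target_rate = 10, window_seconds = 1,
                           step_samples = 10)
  rec <- uniform_record(30, rate = 10)
  # window 1 fully inside class A; window 2: 60/40 split; window 3: 50/50
  tr <- label_track(tibble::tibble(
    t_start = c(0.0, 1.0, 2.0),
    t_end = c(1.0, 1.6, 2.5),
    class = c("Push up", "Push up", "Push up")), "u")
  ws <- segment_windows(rec, cfg)
  ws <- assign_window_labels(ws, tr, 0.5)
  expect_equal(ws$meta$label, c("Push up", "Push up", ood_label()))

  # exact two-class tie -> OOD
  tr2 <- label_track(tibble::tibble(
    t_start = c(0, 0.5), t_end = c(0.5, 1.0),
    class = c("Push up", "Resisted row")), "u")
  ws2 <- assign_window_labels(segment_windows(uniform_record(10, rate = 10),
                                              cfg), tr2, 0.5)
  expect_equal(ws2$meta$label, ood_label())
})

test_that("records split at gaps instead of interpolating across them", {
  df <- mkdf <- data.frame(t = c((0:99) / 50, 5 + (0:99) / 50),
                           ax = rnorm(200), ay = rnorm(200), az = rnorm(200),
                           gx = rnorm(200), gy = rnorm(200), gz = rnorm(200))
  rec <- imu_record(df, "g", "s", 1L, "clinic")
  pieces <- split_at_gaps(rec, max_gap = 1)
  expect_length(pieces, 2L)
  expect_equal(nrow(pieces[[1]]), 100L)
  expect_equal(attr(pieces[[2]], "record_id"), "g.2")
  expect_length(split_at_gaps(uniform_record(100)), 1L)
})

test_that("preprocessing a labelled record is deterministic and labelled", {
  co <- small_cohort()
  rid <- co$manifest$record_id[co$manifest$setting == "clinic"][1]
  entry <- co$records[[rid]]
  ws1 <- preprocess_record(entry$record, entry$track)
  ws2 <- preprocess_record(entry$record, entry$track)
  expect_identical(ws1$windows, ws2$windows)
  expect_true(all(!is.na(ws1$meta$label)))
  expect_equal(ws1$meta$record_id[1], rid)
})
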