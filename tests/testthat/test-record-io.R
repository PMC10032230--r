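mk_record_df <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(t = (seq_len(n) - 1) / 50,
             ax = rnorm(n), ay = rnorm(n), az = rnorm(n) + 9.81,
             gx = rnorm(n), gy = rnorm(n), gz = rnorm(n))
}

test_that("record CSV round-trips within 1e-9", {
  rec <- imu_record(mk_record_df(100), "r1", "s1", 1L, "clinic")
  path <- withr::local_tempfile(fileext = ".csv")
  write_imu_record(rec, path)
  back <- read_imu_record(path, record_id = "r1", subject_id = "s1",
                          session_index = 1L, setting = "clinic")
  expect_equal(as.matrix(back), as.matrix(rec), tolerance = 1e-9)
  expect_equal(attr(back, "dropped_rows"), 0L)
})

test_that("non-finite rows are dropped and counted at read time", {
  df <- mk_record_df(100)
  df$ax[37] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  rec <- read_imu_record(path)
  expect_equal(nrow(rec), 99L)
  expect_equal(attr(rec, "dropped_rows"), 1L)
})

test_that("malformed records raise the specific errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- mk_record_df(10)
  names(df)[2] <- "accel_x"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_imu_record(path), "format error")

  df <- mk_record_df(10)[1, ]
  write.csv(df, path, row.names = FALSE)
  expect_error(read_imu_record(path), "empty-record")

  df <- mk_record_df(10)
  df$t[2] <- df$t[1]            # duplicate timestamp
  write.csv(df, path, row.names = FALSE)
  expect_error(read_imu_record(path), "index 2")
})

test_that("label tracks round-trip and enforce their invariants", {
  iv <- tibble::tibble(t_start = c(0, 5), t_end = c(4, 9),
                       class = c("Resisted row", "Push up"))
  tr <- label_track(iv, "r1")
  path <- withr::local_tempfile(fileext = ".json")
  write_label_track(tr, path)
  back <- read_label_track(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  expect_equal(attr(back, "record_id"), "r1")

  expect_error(label_track(tibble::tibble(t_start = c(0, 2), t_end = c(3, 5),
                                          class = rep("Push up", 2)), "r"),
               "overlap")
  expect_error(label_track(tibble::tibble(t_start = 1, t_end = 1,
                                          class = "Push up"), "r"),
               "t_start < t_end")
  expect_error(label_track(tibble::tibble(t_start = 0, t_end = 1,
                                          class = "Star jump"), "r"),
               "Star jump")
})

test_that("mask materialization follows the half-open convention", {
  tr <- label_track(tibble::tibble(t_start = c(1, 2), t_end = c(2, 3),
                                   class = c("Push up", "Resisted row")), "r")
  t <- c(0, 0.5, 1, 1.5, 1.999, 2, 2.5, 3, 4)
  mask <- label_mask(t, tr)
  expect_equal(length(mask), length(t))
  expect_equal(mask, c("OOD", "OOD", "Push up", "Push up", "Push up",
                       "Resisted row", "Resisted row", "OOD", "OOD"))
})

test_that("manifests round-trip and validation catches missing files", {
  dir <- withr::local_tempdir()
  co <- small_cohort()
  write_cohort(co, dir)
  man <- read_manifest(file.path(dir, "manifest.json"))
  expect_equal(sort(man$record_id), sort(co$manifest$record_id))
  expect_true(all(file.exists(man$record_file)))
  n_clinic_sessions <- dplyr::n_distinct(
    man[man$setting == "clinic", c("subject_id", "session_index")])
  expect_equal(n_clinic_sessions, 6L * 2L)

  man_bad <- man
  man_bad$record_file[1] <- file.path(dir, "records", "missing.csv")
  expect_error(validate_manifest(man_bad), "missing")
})

test_that("a written cohort reads back equivalent", {
  dir <- withr::local_tempdir()
  co <- small_cohort()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  rid <- co$manifest$record_id[5]
  expect_equal(as.matrix(back$records[[rid]]$record),
               as.matrix(co$records[[rid]]$record), tolerance = 1e-9)
  expect_equal(back$records[[rid]]$track$class, co$records[[rid]]$track$class)
  expect_equal(back$manifest$class[back$manifest$record_id == rid],
               co$manifest$class[co$manifest$record_id == rid])
})

test_that("fitted models round-trip through the versioned archive", {
  S <- matrix(rnorm(30), 15, 2)
  det <- calibrate_detector(fit_patient_knn_detector(S, k = 3), S, 0.9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(det, path)
  back <- load_model(path)
  expect_identical(back, det)
  expect_equal(ood_scores(back, S), ood_scores(det, S))
  saveRDS(list(a = 1), path)
  expect_error(load_model(path), "not a model archive")
})
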