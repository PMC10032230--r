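#' @importFrom rlang .data
#' @importFrom stats approx fft kmeans median predict quantile rnorm runif
#'   rlnorm sd setNames var
#' @importFrom utils read.csv write.csv head tail
NULL

RECORD_COLUMNS <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
CHANNEL_NAMES <- c("ax", "ay", "az", "gx", "gy", "gz")

#' Construct an inertial record
#'
#' An inertial record is one continuous wear period of 6-channel smartwatch
#' data: timestamps in seconds relative to record start, 3-axis accelerometer
#' (m/s^2, gravity included) and 3-axis gyroscope (rad/s). It is a tibble with
#' columns `t, ax, ay, az, gx, gy, gz` carrying identity metadata as
#' attributes.
#'
#' @param data Data frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @param record_id,subject_id Identity strings.
#' @param session_index Non-negative integer ordering supervised clinic
#'   sessions; `NA` for at-home records.
#' @param setting `"clinic"` or `"home"`.
#' @param dropped_rows Count of non-finite rows removed at read time.
#' @return An `imu_record` tibble.
#' @export
imu_record <- function(data, record_id, subject_id = "unknown",
                       session_index = NA_integer_, setting = c("clinic", "home"),
                       dropped_rows = 0L) {
  setting <- match.arg(setting)
  if (!identical(names(data), RECORD_COLUMNS)) {
    stop("record must have columns exactly ", paste(RECORD_COLUMNS, collapse = ","),
         "; got ", paste(names(data), collapse = ","))
  }
  out <- tibble::as_tibble(data)
  if (nrow(out) < 2L) stop("empty record: fewer than 2 valid samples")
  bad <- which(diff(out$t) <= 0)
  if (length(bad) > 0L) {
    stop("timestamps not strictly increasing at index ", bad[1L] + 1L)
  }
  if (!all(is.finite(as.matrix(out)))) stop("record contains non-finite values")
  structure(out,
    class = c("imu_record", class(tibble::tibble())),
    record_id = as.character(record_id),
    subject_id = as.character(subject_id),
    session_index = as.integer(session_index),
    setting = setting,
    dropped_rows = as.integer(dropped_rows)
  )
}

#' @export
print.imu_record <- function(x, ...) {
  cat(sprintf("<imu_record %s> subject %s, %s%s, %d samples, %.1f s\n",
              attr(x, "record_id"), attr(x, "subject_id"), attr(x, "setting"),
              if (is.na(attr(x, "session_index"))) ""
              else paste0(" session ", attr(x, "session_index")),
              nrow(x), x$t[nrow(x)] - x$t[1L]))
  NextMethod()
}

record_meta <- function(record) {
  list(record_id = attr(record, "record_id"),
       subject_id = attr(record, "subject_id"),
       session_index = attr(record, "session_index"),
       setting = attr(record, "setting"))
}

#' Read an inertial record from CSV
#'
#' Expects a plain CSV with header exactly `t,ax,ay,az,gx,gy,gz` (`t` in
#' seconds). Rows containing non-finite values are dropped and counted
#' (available as `attr(record, "dropped_rows")`).
#'
#' @param path CSV file path.
#' @inheritParams imu_record
#' @return An [imu_record()].
#' @export
read_imu_record <- function(path, record_id = tools::file_path_sans_ext(basename(path)),
                            subject_id = "unknown", session_index = NA_integer_,
                            setting = "clinic") {
  df <- read.csv(path, colClasses = "numeric")
  if (!identical(names(df), RECORD_COLUMNS)) {
    stop("format error in ", path, ": header must be ",
         paste(RECORD_COLUMNS, collapse = ","), " but is ",
         paste(names(df), collapse = ","))
  }
  keep <- rowSums(!is.finite(as.matrix(df))) == 0L
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2L) stop("empty-record error in ", path, ": < 2 valid rows")
  imu_record(df, record_id = record_id, subject_id = subject_id,
             session_index = session_index, setting = setting,
             dropped_rows = dropped)
}

#' Write an inertial record to CSV
#'
#' @param record An [imu_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_record <- function(record, path) {
  df <- as.data.frame(lapply(record, function(x) format(x, digits = 17, trim = TRUE,
                                                        scientific = FALSE)))
  names(df) <- RECORD_COLUMNS
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a label track
#'
#' Time intervals annotating a record with exercise classes. Intervals follow
#' the half-open convention `[t_start, t_end)`, must not overlap, and every
#' class must resolve in the taxonomy or equal the reserved [ood_label()].
#'
#' @param intervals Tibble/data frame with columns `t_start`, `t_end`, `class`.
#' @param record_id Record the track annotates.
#' @param tax Taxonomy used to resolve class names.
#' @return A `label_track` tibble sorted by `t_start`.
#' @export
label_track <- function(intervals, record_id, tax = taxonomy()) {
  iv <- tibble::as_tibble(intervals)[, c("t_start", "t_end", "class")]
  iv <- dplyr::arrange(iv, .data$t_start)
  if (any(iv$t_start < 0) || any(iv$t_end <= iv$t_start)) {
    stop("label intervals must satisfy 0 <= t_start < t_end")
  }
  if (nrow(iv) > 1L && any(iv$t_start[-1L] < iv$t_end[-nrow(iv)])) {
    stop("label intervals overlap")
  }
  unknown <- setdiff(iv$class, c(tax$exercise, ood_label()))
  if (length(unknown) > 0L) {
    stop("label track uses unknown class(es): ", paste(unknown, collapse = ", "))
  }
  structure(iv, class = c("label_track", class(tibble::tibble())),
            record_id = as.character(record_id))
}

#' Read/write label tracks as JSON sidecars
#'
#' The sidecar format is `{"record_id": ..., "intervals": [[t0, t1, "class"],
#' ...]}`.
#'
#' @param path JSON file path.
#' @param tax Taxonomy used for validation.
#' @return [read_label_track()] returns a `label_track`;
#'   [write_label_track()] returns `path` invisibly.
#' @export
read_label_track <- function(path, tax = taxonomy()) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  iv <- purrr::map_dfr(obj$intervals, function(x) {
    tibble::tibble(t_start = as.numeric(x[[1L]]), t_end = as.numeric(x[[2L]]),
                   class = as.character(x[[3L]]))
  })
  if (nrow(iv) == 0L) iv <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                                           class = character())
  label_track(iv, record_id = obj$record_id, tax = tax)
}

#' @rdname read_label_track
#' @param track A `label_track`.
#' @export
write_label_track <- function(track, path) {
  obj <- list(
    record_id = attr(track, "record_id"),
    intervals = purrr::pmap(track, function(t_start, t_end, class) {
      list(t_start, t_end, class)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Materialize the per-sample class mask of a label track
#'
#' Each timestamp falling inside an interval `[t_start, t_end)` receives that
#' interval's class; timestamps outside every interval receive the reserved
#' [ood_label()].
#'
#' @param timestamps Numeric vector of sample times (seconds).
#' @param track A `label_track`.
#' @return Character vector of classes, one per timestamp.
#' @export
label_mask <- function(timestamps, track) {
  mask <- rep(ood_label(), length(timestamps))
  for (i in seq_len(nrow(track))) {
    inside <- timestamps >= track$t_start[i] & timestamps < track$t_end[i]
    mask[inside] <- track$class[i]
  }
  mask
}

#' Read and validate a dataset manifest
#'
#' A manifest is a flat JSON table organising a dataset's records by subject
#' and session: one entry per record with `record_id`, `subject_id`,
#' `session_index` (null for at-home records), `setting`, `record_file` and
#' optionally `label_file`, with paths relative to the manifest's directory.
#'
#' @param path Manifest JSON path.
#' @param check_files Verify that every referenced file exists.
#' @return A `manifest` tibble; file columns are absolute paths.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  root <- dirname(normalizePath(path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  man <- purrr::map_dfr(obj$records, function(r) {
    tibble::tibble(
      record_id = r$record_id,
      subject_id = r$subject_id,
      session_index = if (is.null(r$session_index)) NA_integer_ else as.integer(r$session_index),
      setting = r$setting,
      record_file = file.path(root, r$record_file),
      label_file = if (is.null(r$label_file)) NA_character_ else file.path(root, r$label_file)
    )
  })
  man <- validate_manifest(man, check_files = check_files)
  man
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
validate_manifest <- function(manifest, check_files = TRUE) {
  stopifnot(all(c("record_id", "subject_id", "session_index", "setting",
                  "record_file", "label_file") %in% names(manifest)))
  if (anyDuplicated(manifest$record_id)) stop("duplicate record_id in manifest")
  if (!all(manifest$setting %in% c("clinic", "home"))) {
    stop("manifest setting must be clinic or home")
  }
  if (any(manifest$setting == "clinic" & is.na(manifest$session_index))) {
    stop("clinic records must carry a session_index")
  }
  if (check_files) {
    paths <- c(manifest$record_file, manifest$label_file)
    paths <- paths[!is.na(paths)]
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop("manifest references missing file(s): ", paste(missing, collapse = ", "))
    }
  }
  structure(tibble::as_tibble(manifest),
            class = c("manifest", class(tibble::tibble())))
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  root <- dirname(normalizePath(path, mustWork = FALSE))
  rel <- function(p) {
    ifelse(is.na(p), NA_character_,
           ifelse(startsWith(p, paste0(root, "/")),
                  substring(p, nchar(root) + 2L), p))
  }
  recs <- purrr::pmap(manifest, function(record_id, subject_id, session_index,
                                         setting, record_file, label_file, ...) {
    r <- list(record_id = record_id, subject_id = subject_id,
              session_index = if (is.na(session_index)) NULL else session_index,
              setting = setting, record_file = rel(record_file))
    if (!is.na(label_file)) r$label_file <- rel(label_file)
    r
  })
  jsonlite::write_json(list(records = recs), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

MODEL_ARCHIVE_VERSION <- "1.0"

#' Save / load fitted models
#'
#' Fitted detectors, classifiers and FCNs are serialized to a single archive
#' carrying a format version tag, the object class and the creation time, so
#' archives can be validated on load.
#'
#' @param object A fitted model (`ood_detector`, `exercise_rf`, `fcn_model`,
#'   `feature_scaler`, ...).
#' @param path Archive path (conventionally `.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored object.
#' @export
save_model <- function(object, path) {
  saveRDS(list(format = "rehabsense-model", version = MODEL_ARCHIVE_VERSION,
               class = class(object)[1L], created = format(Sys.time()),
               object = object),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ar <- readRDS(path)
  if (!is.list(ar) || !identical(ar$format, "rehabsense-model")) {
    stop("not a model archive: ", path)
  }
  if (!identical(ar$version, MODEL_ARCHIVE_VERSION)) {
    warning("model archive version ", ar$version, " (current ",
            MODEL_ARCHIVE_VERSION, ")")
  }
  ar$object
}
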