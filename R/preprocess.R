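#' Preprocessing configuration
#'
#' The smartwatch samples its inertial sensors irregularly at roughly 50 Hz;
#' streams are linearly interpolated onto a uniform 50 Hz grid and segmented
#' with a ten-second sliding window advancing 50 samples (one second) per
#' step, i.e. 90% overlap.
#'
#' @param target_rate Resampling rate in Hz.
#' @param window_seconds Window length in seconds.
#' @param step_samples Window step in samples.
#' @param max_gap Sensor-dropout threshold in seconds: records are split (not
#'   interpolated) across timestamp gaps longer than this.
#' @param majority_fraction A window takes the class covering strictly more
#'   than this fraction of its samples; otherwise it is labelled
#'   [ood_label()].
#' @return A `preprocess_config` list with derived `window_samples`.
#' @export
preprocess_config <- function(target_rate = 50, window_seconds = 10,
                              step_samples = 50, max_gap = 1,
                              majority_fraction = 0.5) {
  L <- as.integer(round(target_rate * window_seconds))
  stopifnot(target_rate > 0, window_seconds > 0,
            step_samples >= 1, step_samples <= L,
            max_gap > 0, majority_fraction > 0, majority_fraction < 1)
  structure(list(target_rate = target_rate, window_seconds = window_seconds,
                 window_samples = L, step_samples = as.integer(step_samples),
                 max_gap = max_gap, majority_fraction = majority_fraction),
            class = "preprocess_config")
}

#' Split a record at sensor-dropout gaps
#'
#' Consecutive timestamps further apart than `max_gap` seconds indicate the
#' watch stopped streaming; interpolating across such a gap would fabricate
#' signal, so the record is split into continuous sub-records instead.
#'
#' @param record An [imu_record()].
#' @param max_gap Gap threshold in seconds.
#' @return A list of `imu_record`s (length 1 when no gap exceeds the
#'   threshold); split pieces get `record_id` suffixes `.1`, `.2`, ...
#' @export
split_at_gaps <- function(record, max_gap = 1) {
  cuts <- which(diff(record$t) > max_gap)
  if (length(cuts) == 0L) return(list(record))
  meta <- record_meta(record)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nrow(record))
  pieces <- purrr::keep(purrr::map2(starts, ends, function(a, b) {
    if (b - a + 1L < 2L) return(NULL)
    as.data.frame(record[a:b, , drop = FALSE])
  }), Negate(is.null))
  purrr::imap(pieces, function(df, i) {
    imu_record(df, record_id = paste0(meta$record_id, ".", i),
               subject_id = meta$subject_id, session_index = meta$session_index,
               setting = meta$setting)
  })
}

#' Resample an irregular record onto a uniform grid
#'
#' Linear interpolation of each channel onto timestamps `0, 1/f, 2/f, ...`
#' (relative to the record's first sample) extending no further than the last
#' input timestamp, so no extrapolation occurs. Already-uniform input starting
#' at zero is returned unchanged up to floating-point error.
#'
#' @param record An [imu_record()].
#' @param target_rate Grid rate in Hz.
#' @return A uniformly sampled `imu_record` (attribute `rate` set).
#' @export
resample_uniform <- function(record, target_rate = 50) {
  t_rel <- record$t - record$t[1L]
  duration <- t_rel[length(t_rel)]
  n_out <- floor(duration * target_rate + 1e-9) + 1L
  if (duration < 2 / target_rate || n_out < 2L) {
    stop("empty-output error: record duration ", signif(duration, 3),
         " s is too short to resample at ", target_rate, " Hz")
  }
  grid <- (seq_len(n_out) - 1L) / target_rate
  cols <- lapply(CHANNEL_NAMES, function(ch) {
    approx(t_rel, record[[ch]], xout = grid, method = "linear", ties = "ordered")$y
  })
  df <- data.frame(t = grid, setNames(cols, CHANNEL_NAMES))
  meta <- record_meta(record)
  out <- imu_record(df, record_id = meta$record_id, subject_id = meta$subject_id,
                    session_index = meta$session_index, setting = meta$setting)
  attr(out, "rate") <- target_rate
  out
}

#' Window set container
#'
#' Fixed-length segments cut from uniformly sampled records, held as a
#' `W x L x 6` array (channel order `ax,ay,az,gx,gy,gz`) alongside a
#' per-window metadata tibble (label, subject, session, source record, start
#' time). `tidy()` returns the metadata.
#'
#' @param windows `W x L x 6` numeric array.
#' @param meta Tibble with one row per window: `record_id`, `subject_id`,
#'   `session_index`, `setting`, `start_time`, `label`.
#' @param rate Sampling rate of the windows in Hz.
#' @return A `window_set`.
#' @export
window_set <- function(windows, meta, rate) {
  stopifnot(length(dim(windows)) == 3L, dim(windows)[3L] == 6L,
            dim(windows)[1L] == nrow(meta))
  structure(list(windows = windows, meta = tibble::as_tibble(meta), rate = rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows x %d samples x 6 channels @ %g Hz\n",
              n_windows(x), dim(x$windows)[2L], x$rate))
  if (n_windows(x) > 0L) print(dplyr::count(x$meta, .data$label))
  invisible(x)
}

#' @export
#' @rdname window_set
#' @param x A `window_set`.
#' @param ... Unused.
tidy.window_set <- function(x, ...) x$meta

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1L]

#' Subset a window set by window index
#' @param ws A `window_set`.
#' @param idx Integer or logical index over windows.
#' @return A `window_set` with the selected windows.
#' @export
ws_subset <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE], ws$meta[idx, , drop = FALSE],
             ws$rate)
}

#' Concatenate window sets
#' @param ... `window_set`s with equal window length and rate.
#' @return A single combined `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- purrr::keep(list(...), function(w) !is.null(w) && n_windows(w) > 0L)
  if (length(sets) == 0L) stop("no non-empty window sets to bind")
  L <- dim(sets[[1L]]$windows)[2L]
  stopifnot(all(vapply(sets, function(w) dim(w$windows)[2L], 1L) == L))
  windows <- array(0, dim = c(sum(vapply(sets, n_windows, 1L)), L, 6L))
  at <- 0L
  for (w in sets) {
    windows[at + seq_len(n_windows(w)), , ] <- w$windows
    at <- at + n_windows(w)
  }
  window_set(windows, dplyr::bind_rows(lapply(sets, function(w) w$meta)),
             sets[[1L]]$rate)
}

#' Sliding-window segmentation of a uniform record
#'
#' Windows of `L = target_rate * window_seconds` samples are taken at sample
#' offsets `0, s, 2s, ...`; a trailing partial window is discarded, giving
#' `floor((N - L)/s) + 1` windows for a record of `N >= L` samples.
#'
#' @param record Uniformly sampled [imu_record()] (from [resample_uniform()]).
#' @param cfg A [preprocess_config()].
#' @return A [window_set()] with `label` set to `NA` (unlabelled).
#' @export
segment_windows <- function(record, cfg = preprocess_config()) {
  rate <- attr(record, "rate")
  if (is.null(rate)) {
    dt <- diff(record$t)
    if (max(abs(dt - dt[1L])) > 1e-6) {
      stop("segment_windows requires a uniformly sampled record; resample first")
    }
    rate <- 1 / dt[1L]
  }
  L <- cfg$window_samples
  s <- cfg$step_samples
  N <- nrow(record)
  meta0 <- record_meta(record)
  if (N < L) {
    warning("record ", meta0$record_id, " shorter than one window (", N, " < ",
            L, " samples); empty window set")
    return(window_set(array(0, dim = c(0L, L, 6L)),
                      tibble::tibble(record_id = character(), subject_id = character(),
                                     session_index = integer(), setting = character(),
                                     start_time = numeric(), label = character()),
                      rate))
  }
  offsets <- seq.int(0L, N - L, by = s)
  X <- as.matrix(record[, CHANNEL_NAMES])
  windows <- array(0, dim = c(length(offsets), L, 6L))
  for (i in seq_along(offsets)) {
    windows[i, , ] <- X[offsets[i] + seq_len(L), ]
  }
  meta <- tibble::tibble(
    record_id = meta0$record_id, subject_id = meta0$subject_id,
    session_index = meta0$session_index, setting = meta0$setting,
    start_time = record$t[offsets + 1L], label = NA_character_
  )
  window_set(windows, meta, rate)
}

#' Assign class labels to windows by strict sample majority
#'
#' Each window takes the class (or [ood_label()]) covering strictly more than
#' `majority_fraction` of its samples under the track's per-sample mask; when
#' no class reaches a strict majority (e.g. an exact tie) the window is
#' labelled [ood_label()].
#'
#' @param ws A [window_set()] from a single record.
#' @param track The record's `label_track`.
#' @param majority_fraction Majority threshold (default 0.5).
#' @return The `window_set` with `label` filled in.
#' @export
assign_window_labels <- function(ws, track, majority_fraction = 0.5) {
  L <- dim(ws$windows)[2L]
  rel <- (seq_len(L) - 1L) / ws$rate
  labels <- vapply(seq_len(n_windows(ws)), function(i) {
    mask <- label_mask(ws$meta$start_time[i] + rel, track)
    tab <- table(mask)
    top <- which.max(tab)
    if (tab[top] > majority_fraction * L) names(tab)[top] else ood_label()
  }, character(1L))
  ws$meta$label <- labels
  ws
}

#' Preprocess one record end to end
#'
#' Splits at dropout gaps, resamples each continuous piece to the target rate,
#' segments into windows and (when a label track is supplied) assigns window
#' labels.
#'
#' @param record An [imu_record()].
#' @param track Optional `label_track`.
#' @param cfg A [preprocess_config()].
#' @return A [window_set()] (possibly empty).
#' @export
preprocess_record <- function(record, track = NULL, cfg = preprocess_config()) {
  pieces <- split_at_gaps(record, cfg$max_gap)
  sets <- list()
  for (piece in pieces) {
    offset <- piece$t[1L]
    res <- tryCatch(resample_uniform(piece, cfg$target_rate), error = function(e) NULL)
    if (is.null(res)) next
    ws <- suppressWarnings(segment_windows(res, cfg))
    if (n_windows(ws) == 0L) next
    # window start times are reported on the original record's clock
    ws$meta$start_time <- ws$meta$start_time + offset
    ws$meta$record_id <- attr(record, "record_id")
    if (!is.null(track)) ws <- assign_window_labels(ws, track, cfg$majority_fraction)
    sets <- c(sets, list(ws))
  }
  if (length(sets) == 0L) {
    return(window_set(array(0, dim = c(0L, cfg$window_samples, 6L)),
                      tibble::tibble(record_id = character(), subject_id = character(),
                                     session_index = integer(), setting = character(),
                                     start_time = numeric(), label = character()),
                      cfg$target_rate))
  }
  do.call(bind_window_sets, sets)
}
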