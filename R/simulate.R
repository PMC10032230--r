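#' Synthetic cohort configuration
#'
#' Defines the simulated study: subjects attending weekly supervised clinic
#' sessions (one short record per exercise set, fully labelled) plus
#' unsupervised at-home records interleaving exercise bouts, rest and
#' activities of daily living (ADL) with exact ground-truth masks, and a
#' separate proxy ADL dataset generated from held-out "proxy subjects" with a
#' different intensity-regime mixture, so the proxy is a deliberately
#' imperfect stand-in for at-home non-exercise data.
#'
#' Repetition periods are drawn from a lognormal moment-matched to mean 3.8 s
#' and SD 2.3 s (right-skewed, as observed in rotator-cuff patients).
#' Accelerometer output includes gravity (9.81 m/s^2), so device orientation
#' during an exercise is a usable class cue; per-subject technique variation
#' is modelled as a random device/limb rotation plus amplitude and speed
#' scaling, with a smaller per-session drift.
#'
#' @param n_subjects,n_sessions Cohort size and supervised sessions each.
#' @param classes Exercise classes simulated; the default 8 span all 6
#'   simple-motion groups.
#' @param classes_per_subject Exercises prescribed to each subject.
#' @param perform_prob Probability a prescribed exercise is performed in a
#'   given session (sessions therefore differ in content, so a test-session
#'   class can lack earlier-session support).
#' @param reps_range Repetitions per bout (uniform over the range).
#' @param period_mean,period_sd Repetition-period distribution (seconds).
#' @param sep Class-separation scale: 0 collapses all exercise templates to
#'   identical (pure gravity) signals.
#' @param subject_sd,session_sd Inter-subject and session-drift variability
#'   (radians of rotation / log-amplitude SD).
#' @param noise_sd Sensor white-noise SD (m/s^2 and rad/s).
#' @param amp_accel,amp_gyro Motion amplitude scales for the two sensors.
#' @param rate Nominal sampling rate (Hz).
#' @param irregular Jitter timestamps by U(-4, 4) ms around the uniform grid,
#'   emulating the watch's asynchronous sampling.
#' @param n_home_records,home_duration At-home records per subject and their
#'   length (seconds).
#' @param n_proxy_subjects,proxy_duration Proxy ADL dataset size.
#' @param gravity Gravitational acceleration (m/s^2).
#' @param seed Master seed; the cohort is a pure function of this config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 12L, n_sessions = 3L,
                          classes = default_classes(),
                          classes_per_subject = 5L, perform_prob = 0.9,
                          reps_range = c(4L, 7L),
                          period_mean = 3.8, period_sd = 2.3,
                          sep = 0.55, subject_sd = 0.32, session_sd = 0.08,
                          noise_sd = 0.5, amp_accel = 3, amp_gyro = 1.5,
                          rate = 50, irregular = TRUE,
                          n_home_records = 1L, home_duration = 240,
                          n_proxy_subjects = 4L, proxy_duration = 240,
                          gravity = 9.81, seed = 1L) {
  stopifnot(n_subjects >= 1, n_sessions >= 1, length(classes) >= 2,
            classes_per_subject >= 1, classes_per_subject <= length(classes),
            period_mean > 0, period_sd >= 0, sep >= 0, subject_sd >= 0,
            session_sd >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_config")
}

#' Default simulated exercise classes
#'
#' Eight taxonomy exercises covering all six simple-motion groups.
#' @return Character vector of exercise names.
#' @export
default_classes <- function() {
  c("Active shoulder flexion", "Active shoulder abduction",
    "Assisted shoulder external rotation", "Resisted shoulder internal rotation",
    "Resisted row", "Resisted triceps pull down", "Resisted lat pull down",
    "Press up against wall")
}

stage_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Draw repetition periods
#'
#' Lognormal moment-matched to the target mean and SD, giving the
#' right-skewed period distribution of slow rehabilitation repetitions.
#'
#' @param n Number of periods.
#' @param mean,sd Target moments in seconds.
#' @return Numeric vector of periods (seconds).
#' @export
draw_periods <- function(n, mean = 3.8, sd = 2.3) {
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function(sd_angle) {
  if (sd_angle == 0) return(diag(3L))
  rotation_matrix(rnorm(3L), rnorm(1L, sd = sd_angle))
}

#' Build per-class motion templates
#'
#' Each class gets a gravity orientation (the device attitude held during the
#' exercise) and three-harmonic amplitude/phase coefficients per channel,
#' scaled by the class-separation parameter `sep`. Classes sharing a
#' simple-motion group draw from a common group-level base, so within-group
#' templates are genuinely more similar than between-group ones — the
#' structural reason grouping eases classification.
#'
#' @param classes Exercise names (must be unique and in the taxonomy).
#' @param sep Class separation; 0 makes all templates identical.
#' @param seed RNG seed.
#' @param tax Taxonomy.
#' @return Named list of templates: `orientation` (unit 3-vector), `amp` and
#'   `phase` (3 harmonics x 6 channels), `group`.
#' @export
make_class_templates <- function(classes, sep = 1, seed = 0L, tax = taxonomy()) {
  if (anyDuplicated(classes)) stop("duplicate class names")
  unknown <- setdiff(classes, tax$exercise)
  if (length(unknown) > 0L) stop("classes not in taxonomy: ",
                                 paste(unknown, collapse = ", "))
  set.seed(seed)
  groups <- tax$simple_motion[match(classes, tax$exercise)]
  decay <- matrix(rep(1 / seq_len(3L), 6L), 3L, 6L)
  # a motion backbone shared by every class: sep scales the class/group
  # deviations from it, so sep = 0 collapses all templates onto one
  # quasi-periodic motion while larger sep separates the classes relative to
  # the (sep-independent) subject variation and sensor noise
  common_amp <- matrix(rnorm(18L), 3L, 6L) * decay
  common_phase <- matrix(runif(18L, 0, 2 * pi), 3L, 6L)
  group_base <- lapply(unique(groups), function(g) {
    list(orient = rnorm(3L),
         amp = matrix(rnorm(18L), 3L, 6L) * decay,
         phase = matrix(rnorm(18L, sd = 0.8), 3L, 6L))
  })
  names(group_base) <- unique(groups)
  templates <- lapply(seq_along(classes), function(i) {
    gb <- group_base[[groups[i]]]
    # group-level structure dominates class-level deviations, so exercises
    # within a simple-motion group are genuinely confusable while groups
    # stay separated — the regime in which grouping eases classification
    o <- c(0, 0, 1) + sep * (0.9 * gb$orient + 0.15 * rnorm(3L))
    amp <- (0.5 + 0.5 * sep) * common_amp +
      sep * (1.2 * gb$amp + 0.2 * matrix(rnorm(18L), 3L, 6L) * decay)
    phase <- common_phase +
      sep * (gb$phase + 0.2 * matrix(rnorm(18L, sd = 0.8), 3L, 6L))
    list(orientation = o / sqrt(sum(o^2)),
         amp = abs(amp),
         phase = phase %% (2 * pi),
         group = groups[i])
  })
  names(templates) <- classes
  templates
}

subject_profile <- function(subject_sd) {
  list(R = random_rotation(subject_sd),
       amp_scale = exp(rnorm(1L, sd = subject_sd)),
       speed_scale = exp(rnorm(1L, sd = subject_sd / 2)))
}

session_modifier <- function(session_sd) {
  list(R = random_rotation(session_sd),
       amp_scale = exp(rnorm(1L, sd = session_sd)))
}

# Evaluate a bout's noiseless signal at arbitrary times (seconds from bout
# start). Returns an n x 6 matrix; samples beyond the last repetition hold
# the static posture.
eval_bout <- function(t, template, periods, R, amp_scale, cfg) {
  bounds <- c(0, cumsum(periods))
  rep_idx <- pmin(pmax(findInterval(t, bounds, rightmost.closed = TRUE), 1L),
                  length(periods))
  phi <- 2 * pi * (t - bounds[rep_idx]) / periods[rep_idx]
  motion <- matrix(0, length(t), 6L)
  for (h in 1:3) {
    for (ch in 1:6) {
      motion[, ch] <- motion[, ch] +
        template$amp[h, ch] * sin(h * phi + template$phase[h, ch])
    }
  }
  motion[t > bounds[length(bounds)], ] <- 0
  acc_motion <- cfg$amp_accel * amp_scale * motion[, 1:3] %*% t(R)
  gyr <- cfg$amp_gyro * amp_scale * motion[, 4:6] %*% t(R)
  grav <- matrix(cfg$gravity * as.numeric(R %*% template$orientation),
                 length(t), 3L, byrow = TRUE)
  cbind(grav + acc_motion, gyr)
}

#' Generate one exercise bout
#'
#' Concatenates `n_reps` repetitions whose periods are drawn from the
#' right-skewed lognormal, evaluated on a (possibly jittered) sampling grid:
#' rotated gravity plus harmonic motion on the accelerometer, harmonic motion
#' on the gyroscope, plus white sensor noise.
#'
#' @param template One entry of [make_class_templates()].
#' @param n_reps Repetitions.
#' @param cfg A [cohort_config()] (rates, amplitudes, noise).
#' @param profile Optional subject profile (rotation, amplitude, speed); NULL
#'   means the canonical performer.
#' @param seed RNG seed.
#' @return List: `t` (seconds), `signal` (n x 6), `duration`, `periods`.
#' @export
generate_bout <- function(template, n_reps, cfg = cohort_config(),
                          profile = NULL, seed = 0L) {
  set.seed(seed)
  if (is.null(profile)) profile <- list(R = diag(3L), amp_scale = 1, speed_scale = 1)
  periods <- draw_periods(n_reps, cfg$period_mean, cfg$period_sd) * profile$speed_scale
  duration <- sum(periods)
  n <- floor(duration * cfg$rate) + 1L
  t <- (seq_len(n) - 1L) / cfg$rate
  if (cfg$irregular && n > 2L) {
    t[2:(n - 1L)] <- t[2:(n - 1L)] + runif(n - 2L, -0.004, 0.004)
  }
  sig <- eval_bout(t, template, periods, profile$R, profile$amp_scale, cfg)
  sig <- sig + matrix(rnorm(n * 6L, sd = cfg$noise_sd), n, 6L)
  list(t = t, signal = sig, duration = duration, periods = periods)
}

# Exact-transition Ornstein-Uhlenbeck sampler at arbitrary time points.
ou_process <- function(t, theta, sigma, x0 = 0) {
  x <- numeric(length(t))
  x[1L] <- x0
  if (length(t) > 1L) {
    dt <- diff(t)
    decay <- exp(-theta * dt)
    sdv <- sigma * sqrt((1 - decay^2) / (2 * theta))
    eps <- rnorm(length(dt))
    for (i in seq_along(dt)) x[i + 1L] <- x[i] * decay[i] + sdv[i] * eps[i]
  }
  x
}

#' Generate a non-exercise (ADL/rest) segment
#'
#' Mean-reverting stochastic motion scaled by `intensity`, under a slowly
#' drifting gravity orientation: intensity 0 gives a near-static rest
#' segment; higher intensities emulate gesturing- or walking-like activity.
#'
#' @param intensity Motion intensity (0 = rest).
#' @param duration Segment length in seconds.
#' @param cfg A [cohort_config()].
#' @param seed RNG seed.
#' @param t Optional explicit time vector (seconds); otherwise a uniform (or
#'   jittered) grid over `duration`.
#' @return List: `t`, `signal` (n x 6).
#' @export
generate_adl_segment <- function(intensity, duration, cfg = cohort_config(),
                                 seed = 0L, t = NULL) {
  set.seed(seed)
  if (is.null(t)) {
    n <- max(2L, floor(duration * cfg$rate) + 1L)
    t <- (seq_len(n) - 1L) / cfg$rate
    if (cfg$irregular && n > 2L) {
      t[2:(n - 1L)] <- t[2:(n - 1L)] + runif(n - 2L, -0.004, 0.004)
    }
  }
  n <- length(t)
  drift <- vapply(1:3, function(i) ou_process(t, theta = 0.3, sigma = 0.15),
                  numeric(n))
  o <- cbind(0, 0, 1)[rep(1L, n), , drop = FALSE] + drift
  o <- o / sqrt(rowSums(o^2))
  acc <- cfg$gravity * o +
    intensity * cfg$amp_accel *
      vapply(1:3, function(i) ou_process(t, theta = 2, sigma = 1), numeric(n))
  gyr <- intensity * cfg$amp_gyro *
    vapply(1:3, function(i) ou_process(t, theta = 2, sigma = 1), numeric(n))
  sig <- cbind(acc, gyr) + matrix(rnorm(n * 6L, sd = cfg$noise_sd), n, 6L)
  list(t = t, signal = sig)
}

# Assemble a record from a list of segments, each
# list(type, duration, class = NULL, fn(t) -> n x 6). Returns record + track.
assemble_record <- function(segments, record_id, subject_id, session_index,
                            setting, cfg) {
  total <- sum(vapply(segments, function(s) s$duration, 1))
  n <- floor(total * cfg$rate) + 1L
  t <- (seq_len(n) - 1L) / cfg$rate
  if (cfg$irregular && n > 2L) {
    t[2:(n - 1L)] <- t[2:(n - 1L)] + runif(n - 2L, -0.004, 0.004)
  }
  sig <- matrix(0, n, 6L)
  intervals <- list()
  at <- 0
  for (s in segments) {
    idx <- which(t >= at & t < at + s$duration)
    if (length(idx) > 0L) sig[idx, ] <- s$fn(t[idx] - at)
    if (!is.null(s$class)) {
      intervals <- c(intervals, list(tibble::tibble(
        t_start = at, t_end = at + s$duration, class = s$class)))
    }
    at <- at + s$duration
  }
  sig <- sig + matrix(rnorm(n * 6L, sd = cfg$noise_sd), n, 6L)
  df <- data.frame(t = t, sig)
  names(df) <- RECORD_COLUMNS
  record <- imu_record(df, record_id = record_id, subject_id = subject_id,
                       session_index = session_index, setting = setting)
  iv <- if (length(intervals) > 0L) dplyr::bind_rows(intervals) else
    tibble::tibble(t_start = numeric(), t_end = numeric(), class = character())
  list(record = record, track = label_track(iv, record_id))
}

bout_segment <- function(class, template, profile, sess, n_reps, cfg) {
  periods <- draw_periods(n_reps, cfg$period_mean, cfg$period_sd) * profile$speed_scale
  R <- sess$R %*% profile$R
  amp <- profile$amp_scale * sess$amp_scale
  list(type = "bout", duration = sum(periods), class = class,
       fn = function(t) eval_bout(t, template, periods, R, amp, cfg))
}

adl_segment_spec <- function(intensity, duration, cfg) {
  seed <- sample.int(2147483646L, 1L)
  list(type = "adl", duration = duration, class = NULL,
       fn = function(t) generate_adl_segment(intensity, duration, cfg,
                                             seed = seed, t = t)$signal)
}

#' Simulate a labelled synthetic cohort
#'
#' Generates, fully deterministically from `cfg$seed`: per subject a
#' prescription of exercises, per session one short clinic record per
#' performed exercise (lead-in/out rest around a labelled bout), per subject
#' at-home records interleaving exercise bouts, rest (including long
#' near-static stretches) and ADL activity with exact ground-truth masks, and
#' a proxy ADL dataset from disjoint proxy subjects with a shifted
#' intensity-regime mixture.
#'
#' @param cfg A [cohort_config()].
#' @return A `synthetic_cohort`: `manifest` (with `class` column), `records`
#'   (named list of `list(record, track)`), `proxy_manifest`,
#'   `proxy_records`, `templates`, `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  templates <- make_class_templates(cfg$classes, sep = cfg$sep,
                                    seed = stage_seed(cfg$seed, "templates"))
  set.seed(stage_seed(cfg$seed, "cohort"))
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  profiles <- lapply(subjects, function(s) subject_profile(cfg$subject_sd))
  names(profiles) <- subjects
  prescriptions <- lapply(subjects, function(s) {
    sample(cfg$classes, cfg$classes_per_subject)
  })
  names(prescriptions) <- subjects

  records <- list()
  rows <- list()
  for (s in subjects) {
    for (sess in seq_len(cfg$n_sessions)) {
      set.seed(stage_seed(cfg$seed, paste0("session-", s, "-", sess)))
      smod <- session_modifier(cfg$session_sd)
      performed <- prescriptions[[s]][runif(cfg$classes_per_subject) < cfg$perform_prob]
      if (length(performed) == 0L) performed <- sample(prescriptions[[s]], 1L)
      for (cls in performed) {
        rid <- sprintf("%s_c%d_%s", s, sess,
                       gsub("[^A-Za-z]+", "", substr(cls, 1, 24)))
        set.seed(stage_seed(cfg$seed, rid))
        n_reps <- sample(seq(cfg$reps_range[1L], cfg$reps_range[2L]), 1L)
        segs <- list(
          adl_segment_spec(0.05, runif(1, 1.5, 3), cfg),
          bout_segment(cls, templates[[cls]], profiles[[s]], smod, n_reps, cfg),
          adl_segment_spec(0.05, runif(1, 1.5, 3), cfg)
        )
        rec <- assemble_record(segs, rid, s, sess, "clinic", cfg)
        records[[rid]] <- rec
        rows[[rid]] <- tibble::tibble(record_id = rid, subject_id = s,
                                      session_index = sess, setting = "clinic",
                                      record_file = NA_character_,
                                      label_file = NA_character_, class = cls)
      }
    }
    for (h in seq_len(cfg$n_home_records)) {
      rid <- sprintf("%s_home%d", s, h)
      set.seed(stage_seed(cfg$seed, rid))
      segs <- list()
      total <- 0
      long_rest_done <- FALSE
      while (total < cfg$home_duration) {
        type <- sample(c("bout", "rest", "adl"), 1L, prob = c(0.4, 0.35, 0.25))
        seg <- switch(type,
          bout = {
            cls <- sample(prescriptions[[s]], 1L)
            n_reps <- sample(seq(cfg$reps_range[1L], cfg$reps_range[2L]), 1L)
            bout_segment(cls, templates[[cls]], profiles[[s]],
                         session_modifier(cfg$session_sd), n_reps, cfg)
          },
          rest = {
            dur <- if (!long_rest_done) { long_rest_done <- TRUE; runif(1, 55, 75) }
                   else runif(1, 8, 45)
            adl_segment_spec(0.03, dur, cfg)
          },
          adl = adl_segment_spec(sample(c(0.4, 0.9, 1.4), 1L), runif(1, 10, 40), cfg)
        )
        segs <- c(segs, list(seg))
        total <- total + seg$duration
      }
      rec <- assemble_record(segs, rid, s, NA_integer_, "home", cfg)
      records[[rid]] <- rec
      rows[[rid]] <- tibble::tibble(record_id = rid, subject_id = s,
                                    session_index = NA_integer_, setting = "home",
                                    record_file = NA_character_,
                                    label_file = NA_character_,
                                    class = NA_character_)
    }
  }

  proxy_records <- list()
  proxy_rows <- list()
  for (p in seq_len(cfg$n_proxy_subjects)) {
    pid <- sprintf("PX%02d", p)
    rid <- sprintf("%s_adl", pid)
    set.seed(stage_seed(cfg$seed, rid))
    segs <- list()
    total <- 0
    while (total < cfg$proxy_duration) {
      seg <- adl_segment_spec(sample(c(0.1, 0.6, 1.1, 1.8), 1L),
                              runif(1, 10, 40), cfg)
      segs <- c(segs, list(seg))
      total <- total + seg$duration
    }
    rec <- assemble_record(segs, rid, pid, NA_integer_, "home", cfg)
    proxy_records[[rid]] <- rec
    proxy_rows[[rid]] <- tibble::tibble(record_id = rid, subject_id = pid,
                                        session_index = NA_integer_,
                                        setting = "home",
                                        record_file = NA_character_,
                                        label_file = NA_character_,
                                        class = NA_character_)
  }

  structure(list(
    config = cfg, templates = templates, prescriptions = prescriptions,
    manifest = dplyr::bind_rows(rows),
    records = records,
    proxy_manifest = dplyr::bind_rows(proxy_rows),
    proxy_records = proxy_records
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d records (%d clinic, %d home), %d proxy records\n",
              length(unique(x$manifest$subject_id)), nrow(x$manifest),
              sum(x$manifest$setting == "clinic"),
              sum(x$manifest$setting == "home"), nrow(x$proxy_manifest)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's file formats
#'
#' Records as CSV, label sidecars as JSON, plus `manifest.json` and
#' `proxy_manifest.json` at the root.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "records"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), showWarnings = FALSE)
  write_one <- function(man, records) {
    for (i in seq_len(nrow(man))) {
      rid <- man$record_id[i]
      rf <- file.path(dir, "records", paste0(rid, ".csv"))
      lf <- file.path(dir, "labels", paste0(rid, ".json"))
      write_imu_record(records[[rid]]$record, rf)
      write_label_track(records[[rid]]$track, lf)
      man$record_file[i] <- rf
      man$label_file[i] <- lf
    }
    man
  }
  man <- write_one(cohort$manifest, cohort$records)
  pman <- write_one(cohort$proxy_manifest, cohort$proxy_records)
  write_manifest(man, file.path(dir, "manifest.json"))
  write_manifest(pman, file.path(dir, "proxy_manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json` and `proxy_manifest.json`.
#' @return A `synthetic_cohort`-compatible list (without generator internals).
#' @export
read_cohort <- function(dir) {
  load_side <- function(man) {
    recs <- lapply(seq_len(nrow(man)), function(i) {
      list(record = read_imu_record(man$record_file[i],
                                    record_id = man$record_id[i],
                                    subject_id = man$subject_id[i],
                                    session_index = man$session_index[i],
                                    setting = man$setting[i]),
           track = read_label_track(man$label_file[i]))
    })
    names(recs) <- man$record_id
    recs
  }
  man <- read_manifest(file.path(dir, "manifest.json"))
  pman <- read_manifest(file.path(dir, "proxy_manifest.json"))
  structure(list(manifest = manifest_record_classes(man),
                 records = load_side(man),
                 proxy_manifest = pman,
                 proxy_records = load_side(pman)),
            class = "synthetic_cohort")
}

#' The default benchmark cohort
#'
#' The fixed-seed cohort used throughout the package's end-to-end checks:
#' 12 subjects, 3 supervised sessions, the 8 default classes.
#'
#' @return A `synthetic_cohort`.
#' @export
benchmark_cohort <- function() simulate_cohort(cohort_config())
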