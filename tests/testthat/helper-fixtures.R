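# Shared fixtures and independent oracle implementations.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# small synthetic cohort for plumbing tests (seconds to generate)
small_cohort <- function() {
  cached("small_cohort", simulate_cohort(cohort_config(
    n_subjects = 6L, n_sessions = 2L, home_duration = 100,
    n_proxy_subjects = 2L, proxy_duration = 100, seed = 42L)))
}

# the package's default fixed-seed benchmark cohort (shared across
# acceptance checks; generated once per test run)
bench_cohort <- function() cached("bench_cohort", benchmark_cohort())

bench_pre <- function() cached("bench_pre", preprocess_cohort(bench_cohort()))

# window set with class-dependent signal structure, separable by construction
toy_window_set <- function(n, L = 40L, labels = rep(c("sine", "const"),
                                                    length.out = n),
                           noise = 0.3, seed = 1L) {
  set.seed(seed)
  arr <- array(rnorm(n * L * 6L, sd = noise), dim = c(n, L, 6L))
  for (i in seq_len(n)) {
    f <- if (labels[i] == "sine") sin(6 * pi * seq_len(L) / L) else
      rep(1, L)
    for (ch in 1:3) arr[i, , ch] <- arr[i, , ch] + f
  }
  window_set(arr, tibble::tibble(record_id = "toy", subject_id = "s",
                                 session_index = 1L, setting = "clinic",
                                 start_time = 0, label = labels), 50)
}

meta1 <- function(n = 1L) {
  tibble::tibble(record_id = "r", subject_id = "s", session_index = 1L,
                 setting = "clinic", start_time = 0,
                 label = NA_character_)[rep(1L, n), ]
}

as_ws <- function(arr) window_set(arr, meta1(dim(arr)[1L]), 50)

# separable 2-D gaussian blob features for detector/classifier tests
blob_features <- function(n_per, centers, sd = 0.2, seed = 1L) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1L], sd), rnorm(n_per, centers[i, 2L], sd))
  }))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(rownames(centers) %||% LETTERS[seq_len(nrow(centers))],
                      each = n_per))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles -------------------------------------------------

oracle_features_1ch <- function(x) {
  L <- length(x)
  mu <- sum(x) / L
  d <- x - mu
  m2 <- sum(d^2) / L
  m3 <- sum(d^3) / L
  m4 <- sum(d^4) / L
  s <- sign(d)
  cr <- 0L
  for (i in seq_len(L - 1L)) if (s[i] * s[i + 1L] < 0) cr <- cr + 1L
  c(median = as.numeric(stats::median(x)),
    rms = sqrt(sum(x^2) / L),
    sd = sqrt(m2), var = m2, min = min(x), max = max(x),
    skew = if (m2 > 0) m3 / m2^1.5 else 0,
    kurt = if (m2 > 0) m4 / m2^2 - 3 else 0,
    spec_energy = mean(Mod(stats::fft(x))^2),   # direct DFT definition
    mean_crossings = cr)
}

auroc_brute <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
}

knn_mean_dist_brute <- function(q, S, k) {
  d <- sqrt(rowSums((S - matrix(q, nrow(S), length(q), byrow = TRUE))^2))
  mean(sort(d)[seq_len(min(k, length(d)))])
}

kmeans_score_brute <- function(q, centers) {
  min(sqrt(rowSums((centers - matrix(q, nrow(centers), length(q),
                                     byrow = TRUE))^2)))
}

calibrate_brute <- function(scores, target) {
  for (tau in sort(unique(scores))) {
    if (mean(scores <= tau) >= target) return(tau)
  }
  max(scores)
}

count_windows_brute <- function(N, L, s) {
  n <- 0L
  o <- 0L
  while (o + L <= N) {
    n <- n + 1L
    o <- o + s
  }
  n
}

# random manifest tibble (no files needed: class column present)
random_manifest <- function(seed) {
  set.seed(seed)
  n_subj <- sample(5:9, 1L)
  classes <- sample(taxonomy()$exercise, 6L)
  rows <- list()
  for (s in seq_len(n_subj)) {
    n_sess <- sample(2:4, 1L)
    for (se in seq_len(n_sess)) {
      for (cls in sample(classes, sample(2:4, 1L))) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          record_id = sprintf("S%d_%d_%s_%d", s, se,
                              substr(gsub(" ", "", cls), 1, 8),
                              length(rows)),
          subject_id = sprintf("S%d", s), session_index = se,
          setting = "clinic", record_file = NA_character_,
          label_file = NA_character_, class = cls)
      }
    }
  }
  dplyr::bind_rows(rows)
}
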