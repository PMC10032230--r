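FEATURE_NAMES <- c("median", "rms", "sd", "var", "min", "max", "skew", "kurt",
                   "spec_energy", "mean_crossings")

#' Engineered statistical features of one window
#'
#' Ten statistics per sensor channel: median, root-mean-square (absolute
#' energy), standard deviation and variance (population, denominator `L`),
#' minimum, maximum, moment-based skewness (`m3 / m2^1.5`, 0 for a constant
#' channel), excess kurtosis (`m4 / m2^2 - 3`, 0 for a constant channel), mean
#' spectral energy (mean over all `L` DFT bins of the squared magnitude,
#' which by Parseval's identity equals `L * mean(x^2)`), and mean crossings
#' (consecutive sample pairs whose values sit on strictly opposite sides of
#' the channel mean).
#'
#' @param window `L x 6` numeric matrix, channel order `ax,ay,az,gx,gy,gz`.
#' @return Named numeric vector of length 60 (`<channel>_<feature>`).
#' @export
engineered_features <- function(window) {
  stopifnot(is.matrix(window), ncol(window) == 6L, nrow(window) >= 2L)
  ws <- window_set(array(window, dim = c(1L, nrow(window), 6L)),
                   tibble::tibble(record_id = "w", subject_id = "w",
                                  session_index = NA_integer_, setting = "clinic",
                                  start_time = 0, label = NA_character_),
                   rate = 50)
  X <- engineered_feature_matrix(ws)
  setNames(as.numeric(X[1L, ]), colnames(X))
}

engineered_feature_matrix <- function(ws) {
  W <- n_windows(ws)
  L <- dim(ws$windows)[2L]
  out <- matrix(0, W, 60L)
  cn <- character(60L)
  for (c in seq_len(6L)) {
    M <- ws$windows[, , c, drop = FALSE]
    dim(M) <- c(W, L)
    if (!all(is.finite(M))) {
      stop("non-finite values in channel ", CHANNEL_NAMES[c])
    }
    mu <- rowMeans(M)
    D <- M - mu
    m2 <- rowMeans(D^2)
    m3 <- rowMeans(D^3)
    m4 <- rowMeans(D^4)
    skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
    kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
    s <- sign(D)
    crossings <- rowSums(s[, -L, drop = FALSE] * s[, -1L, drop = FALSE] < 0)
    block <- cbind(
      apply(M, 1L, median),
      sqrt(rowMeans(M^2)),
      sqrt(m2),
      m2,
      apply(M, 1L, min),
      apply(M, 1L, max),
      skew,
      kurt,
      rowSums(M^2),          # Parseval: mean_k |X_k|^2 = sum_i x_i^2
      crossings
    )
    cols <- (c - 1L) * 10L + seq_len(10L)
    out[, cols] <- block
    cn[cols] <- paste(CHANNEL_NAMES[c], FEATURE_NAMES, sep = "_")
  }
  colnames(out) <- cn
  out
}

#' Extract per-window features as a tibble
#'
#' Computes the 60 engineered statistics for every window and returns them
#' alongside the window metadata, ready to pipe into detector/classifier
#' fitting.
#'
#' @param ws A [window_set()].
#' @return A `feature_tbl`: metadata columns plus one column per feature;
#'   attribute `feature_cols` names the feature columns and `extractor`
#'   records the extractor identity.
#' @examples
#' rec <- simulate_cohort(cohort_config(n_subjects = 2, seed = 1))$records[[1]]
#' ws <- preprocess_record(rec$record, rec$track)
#' extract_features(ws)
#' @export
extract_features <- function(ws) {
  X <- engineered_feature_matrix(ws)
  out <- dplyr::bind_cols(ws$meta, tibble::as_tibble(X))
  structure(out, class = c("feature_tbl", class(tibble::tibble())),
            feature_cols = colnames(X), extractor = "engineered")
}

#' Numeric feature matrix of a feature tibble
#' @param X A `feature_tbl`.
#' @return Numeric matrix of the feature columns only.
#' @export
feature_values <- function(X) {
  fc <- attr(X, "feature_cols")
  stopifnot(!is.null(fc))
  as.matrix(as.data.frame(X)[, fc, drop = FALSE])
}

as_feature_tbl <- function(meta, X, extractor) {
  out <- dplyr::bind_cols(meta, tibble::as_tibble(X))
  structure(out, class = c("feature_tbl", class(tibble::tibble())),
            feature_cols = colnames(X), extractor = extractor)
}

#' Fit / apply a train-split z-score scaler
#'
#' Distance-based detectors (KMeans, KNN) compare features with a Euclidean
#' metric, so columns are standardized to mean 0 / SD 1 using statistics from
#' the training rows only; zero-variance columns map to 0. Tree models are
#' unaffected by the affine map, so the same scaled matrix feeds every model.
#'
#' @param X A `feature_tbl`.
#' @param train_rows Integer or logical index of the training rows.
#' @return `fit_scaler()` returns a `feature_scaler`; `apply_scaler()` the
#'   scaled `feature_tbl`.
#' @export
fit_scaler <- function(X, train_rows = seq_len(nrow(X))) {
  M <- feature_values(X)[train_rows, , drop = FALSE]
  if (nrow(M) == 0L) stop("fit_scaler needs at least one training row")
  ctr <- colMeans(M)
  scl <- sqrt(colMeans(sweep(M, 2L, ctr)^2))  # population SD
  structure(list(center = ctr, scale = scl,
                 feature_cols = attr(X, "feature_cols")),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler` from [fit_scaler()].
#' @export
apply_scaler <- function(X, scaler) {
  if (!inherits(scaler, "feature_scaler")) {
    stop("state error: apply_scaler requires a fitted feature_scaler")
  }
  M <- feature_values(X)
  stopifnot(identical(colnames(M), scaler$feature_cols))
  sc <- ifelse(scaler$scale > 0, scaler$scale, Inf)  # zero-variance -> 0
  M <- sweep(sweep(M, 2L, scaler$center), 2L, sc, "/")
  meta <- as.data.frame(X)[, setdiff(names(X), scaler$feature_cols), drop = FALSE]
  as_feature_tbl(tibble::as_tibble(meta), M, attr(X, "extractor"))
}
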