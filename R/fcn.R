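#' Fully convolutional network configuration
#'
#' The standard time-series FCN: three 1-D convolution blocks of 128, 256 and
#' 128 filters with kernel sizes 8, 5 and 3, each followed by batch
#' normalization and ReLU, then global average pooling and a linear softmax
#' layer. The pooled 128-wide activation is the "embedding" used as a learned
#' feature representation. Trained with Adam and cross-entropy.
#'
#' @param epochs Training epochs (150 reproduces the reference setting; tests
#'   and the bundled benchmark use far fewer).
#' @param batch_size Windows per optimizer step.
#' @param learning_rate Adam step size.
#' @param filters,kernels Per-block filter counts and kernel widths. The
#'   defaults are the fixed architecture; overriding them is intended only for
#'   tiny numerical checks.
#' @param ghost_size Batch-normalization sub-batch: each optimizer batch is
#'   processed in sub-batches of this size whose own statistics drive the
#'   normalization, bounding peak memory at the full 500-sample window size.
#' @param seed RNG seed for initialization and shuffling.
#' @return An `fcn_config` list.
#' @export
fcn_config <- function(epochs = 150, batch_size = 256, learning_rate = 1e-4,
                       filters = c(128L, 256L, 128L), kernels = c(8L, 5L, 3L),
                       ghost_size = 64L, seed = 0L) {
  stopifnot(length(filters) == 3L, length(kernels) == 3L, epochs >= 1,
            batch_size >= 2, ghost_size >= 2, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, filters = as.integer(filters),
                 kernels = as.integer(kernels),
                 ghost_size = as.integer(min(ghost_size, batch_size)),
                 seed = as.integer(seed)),
            class = "fcn_config")
}

# ---- parameter initialisation --------------------------------------------

init_fcn_params <- function(c_in, n_classes, cfg) {
  f <- cfg$filters; k <- cfg$kernels
  he <- function(fan_in, n_out) {
    matrix(rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
  }
  c_ins <- c(c_in, f[1L], f[2L])
  p <- list()
  for (i in 1:3) {
    p[[paste0("W", i)]] <- he(c_ins[i] * k[i], f[i])
    p[[paste0("b", i)]] <- numeric(f[i])
    p[[paste0("g", i)]] <- rep(1, f[i])
    p[[paste0("be", i)]] <- numeric(f[i])
  }
  lim <- sqrt(6 / (f[3L] + n_classes))
  p$Wd <- matrix(runif(f[3L] * n_classes, -lim, lim), f[3L], n_classes)
  p$bd <- numeric(n_classes)
  p
}

# column-broadcast arithmetic for small matrices
crep <- function(v, n) rep(v, each = n)

# Forward one chunk. X: B x L x C_in (already channel-normalized).
# Activations live as flat (B*L) x C matrices (window index fastest);
# convolutions run as offset-BLAS kernels on that layout.
fcn_forward <- function(p, X, cfg, bn, training = FALSE, keep_cache = FALSE) {
  B <- dim(X)[1L]; L <- dim(X)[2L]
  A <- X
  dim(A) <- c(B * L, dim(X)[3L])
  caches <- vector("list", 3L)
  bn_batch <- vector("list", 3L)
  for (i in 1:3) {
    K <- cfg$kernels[i]
    pl <- (K - 1L) %/% 2L
    C <- ncol(A)
    Y <- conv1d_forward_cpp(A, p[[paste0("W", i)]], p[[paste0("b", i)]], B, L, pl)
    if (training) {
      bnc <- bn_forward_train_cpp(Y, p[[paste0("g", i)]], p[[paste0("be", i)]],
                                  1e-5)
      A2 <- relu_cpp(bnc$out)
      bn_batch[[i]] <- list(mu = bnc$mean, v = bnc$var)
      if (keep_cache) {
        caches[[i]] <- list(A_in = A, xhat = bnc$xhat, invstd = bnc$invstd,
                            A_out = A2, C = C, K = K, pl = pl)
      }
    } else {
      invstd <- 1 / sqrt(pmax(bn$var[[i]], 0) + 1e-5)
      a <- p[[paste0("g", i)]] * invstd
      A2 <- relu_cpp(col_affine_cpp(Y, a, p[[paste0("be", i)]] - a * bn$mean[[i]]))
    }
    A <- A2
  }
  # global average pooling over time
  E <- rowsum(A, group = rep_len(seq_len(B), B * L), reorder = TRUE) / L
  rownames(E) <- NULL
  logits <- E %*% p$Wd + crep(p$bd, B)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  P <- ex / rowSums(ex)
  list(P = P, E = E, logits = logits, caches = caches, B = B, L = L,
       bn_batch = if (training) bn_batch else NULL)
}

# Backward one chunk; dlogits already scaled by 1/(total batch size).
fcn_backward <- function(p, fw, dlogits, cfg) {
  B <- fw$B; L <- fw$L
  g <- list()
  g$Wd <- crossprod(fw$E, dlogits)
  g$bd <- colSums(dlogits)
  dE <- dlogits %*% t(p$Wd)
  dA <- dE[rep(seq_len(B), times = L), , drop = FALSE] / L
  for (i in 3:1) {
    cc <- fw$caches[[i]]
    dA <- relu_backward_cpp(dA, cc$A_out)
    bb <- bn_backward_cpp(dA, cc$xhat, p[[paste0("g", i)]] * cc$invstd)
    g[[paste0("g", i)]] <- bb$dg
    g[[paste0("be", i)]] <- bb$dbe
    dY <- bb$dY
    g[[paste0("W", i)]] <- conv1d_grad_weights_cpp(cc$A_in, dY, B, L, cc$pl, cc$K)
    g[[paste0("b", i)]] <- colSums(dY)
    if (i > 1L) {
      dA <- conv1d_backward_data_cpp(dY, p[[paste0("W", i)]], B, L, cc$pl, cc$C)
    }
  }
  g
}

#' Train the fully convolutional network on labelled windows
#'
#' Windows are z-normalized per channel with training-set statistics, then the
#' three-block FCN is fitted by Adam on cross-entropy, deterministic under
#' `cfg$seed`. Batch-normalization statistics inside each optimizer batch are
#' computed on sub-batches of `cfg$ghost_size` windows; running averages of
#' those statistics are used at prediction time.
#'
#' @param ws A labelled [window_set()], or a `B x L x 6` array with `labels`.
#' @param labels Window labels (defaults to `ws$meta$label`); at least two
#'   classes must be present.
#' @param cfg An [fcn_config()].
#' @return An `fcn_model` with weights, class order, per-channel
#'   normalization statistics, per-epoch mean training loss (`history`) and
#'   the config snapshot.
#' @export
fit_fcn <- function(ws, labels = NULL, cfg = fcn_config()) {
  X <- if (inherits(ws, "window_set")) ws$windows else ws
  if (is.null(labels) && inherits(ws, "window_set")) labels <- ws$meta$label
  stopifnot(length(dim(X)) == 3L, dim(X)[1L] == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("fit_fcn needs at least 2 classes")
  y <- match(labels, classes)
  B_all <- dim(X)[1L]; L <- dim(X)[2L]; C_in <- dim(X)[3L]

  ch_mean <- apply(X, 3L, mean)
  ch_sd <- apply(X, 3L, sd)
  ch_sd[ch_sd == 0] <- 1
  for (c in seq_len(C_in)) X[, , c] <- (X[, , c] - ch_mean[c]) / ch_sd[c]

  set.seed(cfg$seed)
  p <- init_fcn_params(C_in, length(classes), cfg)
  bn <- list(mean = lapply(cfg$filters, function(f) numeric(f)),
             var = lapply(cfg$filters, function(f) rep(1, f)))
  mom <- 0.9
  adam <- list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
               t = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(B_all)
    ep_loss <- 0
    starts <- seq.int(1L, B_all, by = cfg$batch_size)
    for (st in starts) {
      idx <- ord[st:min(st + cfg$batch_size - 1L, B_all)]
      nb <- length(idx)
      grads <- NULL
      chunk_starts <- seq.int(1L, nb, by = cfg$ghost_size)
      for (cs in chunk_starts) {
        cidx <- idx[cs:min(cs + cfg$ghost_size - 1L, nb)]
        Xc <- X[cidx, , , drop = FALSE]
        fw <- fcn_forward(p, Xc, cfg, bn, training = TRUE, keep_cache = TRUE)
        for (i in 1:3) {
          bn$mean[[i]] <- mom * bn$mean[[i]] + (1 - mom) * fw$bn_batch[[i]]$mu
          bn$var[[i]] <- mom * bn$var[[i]] + (1 - mom) * fw$bn_batch[[i]]$v
        }
        pr <- fw$P[cbind(seq_along(cidx), y[cidx])]
        ep_loss <- ep_loss - sum(log(pmax(pr, 1e-12)))
        dlogits <- fw$P
        dlogits[cbind(seq_along(cidx), y[cidx])] <-
          dlogits[cbind(seq_along(cidx), y[cidx])] - 1
        dlogits <- dlogits / nb
        gch <- fcn_backward(p, fw, dlogits, cfg)
        grads <- if (is.null(grads)) gch else
          purrr::map2(grads, gch[names(grads)], `+`)
      }
      adam$t <- adam$t + 1L
      for (nm in names(p)) {
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * grads[[nm]]
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - b1^adam$t)
        vhat <- adam$v[[nm]] / (1 - b2^adam$t)
        p[[nm]] <- p[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    history[epoch] <- ep_loss / B_all
  }

  structure(list(params = p, bn = bn, classes = classes, config = cfg,
                 channel_mean = ch_mean, channel_sd = ch_sd, history = history),
            class = "fcn_model")
}

fcn_infer <- function(model, X, what = c("proba", "embedding", "both")) {
  what <- match.arg(what)
  if (inherits(X, "window_set")) X <- X$windows
  stopifnot(inherits(model, "fcn_model"), length(dim(X)) == 3L)
  for (c in seq_len(dim(X)[3L])) {
    X[, , c] <- (X[, , c] - model$channel_mean[c]) / model$channel_sd[c]
  }
  B <- dim(X)[1L]
  P <- E <- NULL
  for (st in seq.int(1L, B, by = 64L)) {
    idx <- st:min(st + 63L, B)
    fw <- fcn_forward(model$params, X[idx, , , drop = FALSE], model$config,
                      model$bn, training = FALSE, keep_cache = FALSE)
    if (what != "embedding") P <- rbind(P, fw$P)
    if (what != "proba") E <- rbind(E, fw$E)
  }
  switch(what, proba = P, embedding = E, both = list(proba = P, embedding = E))
}

#' Class probabilities and embeddings from a fitted FCN
#'
#' `predict_proba()` returns the softmax class probabilities (rows sum to 1);
#' `fcn_embeddings()` returns the penultimate-layer representation, i.e. the
#' global-average-pooled pre-softmax activations (width 128 under the default
#' architecture).
#'
#' @param model A fitted `fcn_model`.
#' @param ws A [window_set()] or `B x L x 6` array.
#' @return `predict_proba()`: `B x n_classes` matrix with class-name columns;
#'   `fcn_embeddings()`: `B x 128` matrix.
#' @export
predict_proba <- function(model, ws) {
  P <- fcn_infer(model, ws, "proba")
  colnames(P) <- model$classes
  P
}

#' @rdname predict_proba
#' @export
fcn_embeddings <- function(model, ws) fcn_infer(model, ws, "embedding")

#' @rdname predict_proba
#' @details `fcn_outputs()` computes both in a single forward pass.
#' @export
fcn_outputs <- function(model, ws) {
  out <- fcn_infer(model, ws, "both")
  colnames(out$proba) <- model$classes
  out
}

#' @export
predict.fcn_model <- function(object, newdata, ...) {
  P <- predict_proba(object, newdata)
  object$classes[max.col(P, ties.method = "first")]
}

#' Embedding features as a feature tibble
#'
#' Wraps [fcn_embeddings()] in the same tabular container as
#' [extract_features()], so embeddings and engineered statistics are
#' interchangeable downstream.
#'
#' @inheritParams predict_proba
#' @return A `feature_tbl` with columns `emb_001 ...`.
#' @export
fcn_features <- function(model, ws) {
  E <- fcn_embeddings(model, ws)
  colnames(E) <- sprintf("emb_%03d", seq_len(ncol(E)))
  as_feature_tbl(ws$meta, E, extractor = "fcn_embedding")
}

#' @export
#' @rdname fit_fcn
#' @param x A fitted `fcn_model`.
#' @param ... Unused.
glance.fcn_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), epochs = x$config$epochs,
                 final_loss = x$history[length(x$history)],
                 embedding_width = x$config$filters[3L])
}

#' @export
tidy.fcn_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), loss = x$history)
}
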