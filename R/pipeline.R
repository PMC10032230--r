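DETECTOR_KINDS <- c("kmeans_engineered", "kmeans_embedding", "softmax",
                    "patient_knn_engineered", "patient_knn_embedding",
                    "proxy_rf_engineered", "proxy_rf_embedding", "proxy_fcn",
                    "proxy_patient_knn_engineered", "proxy_patient_knn_embedding")
CLASSIFIER_KINDS <- c("rf_engineered", "rf_embedding", "fcn",
                      "patient_knn_engineered", "patient_knn_embedding")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiment configuration
#'
#' Declares the method grid (detector and classifier kinds, grouping levels),
#' the evaluation protocol, and all stage sub-configurations. The global
#' `seed` is fanned out to per-stage seeds via a hash of the stage name, so
#' stages draw independent but reproducible streams.
#'
#' @param detectors Detector kinds (subset of the ten supported; see
#'   [ood_detectors]). Suffixes `_engineered`/`_embedding` select the feature
#'   space; `softmax`, `proxy_fcn` and any `_embedding` kind require the FCN.
#' @param classifiers Classifier kinds.
#' @param groupings Grouping levels to evaluate (classifiers and
#'   class-count-linked detectors are trained per level, labels mapped before
#'   fitting).
#' @param n_folds Cross-validation folds (subject-wise).
#' @param folds Folds to actually run (default all); a single fold gives one
#'   train/test split.
#' @param sensitivity_target Calibration sensitivity floor (0.90).
#' @param standardize Fit a train-split z-score scaler and feed standardized
#'   features to every model (distance methods need it; trees are unaffected).
#' @param fcn [fcn_config()] used for embedding/softmax/proxy-FCN methods.
#' @param max_fcn_train Cap on FCN training windows per fold (seeded
#'   subsample), bounding training cost.
#' @param preprocess A [preprocess_config()].
#' @param eval_home Evaluate detectors on the at-home records of test-fold
#'   subjects (per-record metrics, averaged within fold).
#' @param seed Global experiment seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(detectors = c("kmeans_engineered",
                                            "patient_knn_engineered",
                                            "proxy_rf_engineered"),
                              classifiers = c("rf_engineered",
                                              "patient_knn_engineered"),
                              groupings = c("exercise", "simple_motion"),
                              n_folds = 5L, folds = NULL,
                              sensitivity_target = 0.90, standardize = TRUE,
                              fcn = fcn_config(epochs = 8L),
                              max_fcn_train = 600L,
                              preprocess = preprocess_config(),
                              eval_home = TRUE, seed = 0L) {
  stopifnot(all(detectors %in% DETECTOR_KINDS),
            all(classifiers %in% CLASSIFIER_KINDS),
            all(groupings %in% grouping_levels()))
  structure(list(detectors = detectors, classifiers = classifiers,
                 groupings = groupings, n_folds = as.integer(n_folds),
                 folds = folds, sensitivity_target = sensitivity_target,
                 standardize = standardize, fcn = fcn,
                 max_fcn_train = as.integer(max_fcn_train),
                 preprocess = preprocess, eval_home = eval_home,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

needs_fcn <- function(cfg) {
  any(grepl("embedding|fcn|softmax", c(cfg$detectors, cfg$classifiers)))
}

#' Preprocess every record of a cohort into window sets
#'
#' Resamples, segments and labels all clinic, home and proxy records. Proxy
#' windows carry [ood_label()]; home windows carry ground-truth window labels
#' derived from the generator's masks.
#'
#' @param cohort A `synthetic_cohort` (or compatible list).
#' @param pcfg A [preprocess_config()].
#' @return List: `clinic` (one labelled [window_set()]), `home` (list of
#'   window sets, one per home record), `proxy` (one window set).
#' @export
preprocess_cohort <- function(cohort, pcfg = preprocess_config()) {
  do_records <- function(records, man) {
    sets <- purrr::map(man$record_id, function(rid) {
      entry <- records[[rid]]
      ws <- preprocess_record(entry$record, entry$track, pcfg)
      if (n_windows(ws) == 0L) NULL else ws
    })
    purrr::compact(sets)
  }
  man <- cohort$manifest
  clinic_sets <- do_records(cohort$records, man[man$setting == "clinic", ])
  home_sets <- do_records(cohort$records, man[man$setting == "home", ])
  proxy_sets <- do_records(cohort$proxy_records, cohort$proxy_manifest)
  list(clinic = do.call(bind_window_sets, clinic_sets),
       home = home_sets,
       proxy = do.call(bind_window_sets, proxy_sets))
}

subsample_idx <- function(idx, max_n, seed) {
  if (length(idx) <= max_n) return(idx)
  set.seed(seed)
  sort(sample(idx, max_n))
}

feat_of <- function(kind) if (grepl("embedding", kind)) "emb" else "eng"

# Fit + calibrate one pooled detector kind inside a fold context (fx).
fit_fold_detector <- function(kind, fx, cfg, fold, grouping) {
  feat <- feat_of(kind)
  base_kind <- sub("_(engineered|embedding)$", "", kind)
  seed <- stage_seed(cfg$seed, paste0("det-", kind, "-", fold, "-", grouping))
  tr_id <- fx$tr_id
  target <- cfg$sensitivity_target
  switch(base_kind,
    kmeans = {
      n_cl <- length(unique(fx$lab_g[tr_id]))
      det <- fit_kmeans_detector(fx$feats[[feat]][tr_id, , drop = FALSE],
                                 n_clusters = n_cl, seed = seed)
      calibrate_detector(det, fx$feats[[feat]][tr_id, , drop = FALSE], target)
    },
    softmax = {
      det <- fit_softmax_detector(fx$fcn_id)
      det$threshold <- calibrate_threshold(fx$softmax_scores[tr_id], target)
      det$calibration <- list(
        sensitivity_target = target,
        achieved_sensitivity = mean(fx$softmax_scores[tr_id] <= det$threshold),
        n_scores = length(tr_id), loo = FALSE)
      det
    },
    proxy_rf = {
      X <- rbind(fx$feats[[feat]][fx$tr_idx, , drop = FALSE],
                 fx$proxy_train[[feat]])
      y <- c(fx$lab_g[fx$tr_idx], rep(ood_label(), nrow(fx$proxy_train[[feat]])))
      det <- fit_proxy_detector(X, y, base = "random_forest", seed = seed)
      calibrate_detector(det, sensitivity_target = target, oob = TRUE)
    },
    proxy_fcn = {
      det <- new_detector("proxy_fcn", list(model = fx$fcn_proxy))
      det$threshold <- calibrate_threshold(fx$proxy_fcn_scores[tr_id], target)
      det$calibration <- list(
        sensitivity_target = target,
        achieved_sensitivity = mean(fx$proxy_fcn_scores[tr_id] <= det$threshold),
        n_scores = length(tr_id), loo = FALSE)
      det
    },
    stop("unhandled pooled detector kind ", kind)
  )
}

# Score arbitrary windows with a fitted pooled detector. `data` is a list
# with `eng` (matrix), `emb` (matrix or NULL) and `ws` (window_set).
detector_scores_on <- function(det, kind, data) {
  if (det$kind %in% c("softmax", "proxy_fcn")) {
    ood_scores(det, data$ws)
  } else {
    ood_scores(det, data[[feat_of(kind)]])
  }
}

score_eval <- function(scores, positive, threshold) {
  keep <- scores <= threshold
  bm <- binary_metrics(keep, positive)
  list(auroc = auroc(-scores, positive), f1 = bm$f1,
       sensitivity = bm$sensitivity, specificity = bm$specificity)
}

# Materialize the training context of one fold: index sets, standardized
# engineered features, and (when the method grid needs it) the FCN, its
# embeddings and softmax/proxy scores over all clinic windows.
build_fold_context <- function(fold, ctx, cfg) {
  plan <- ctx$plan
  meta <- ctx$pre$clinic$meta
  te <- cv_test_records(plan, fold)
  tr <- cv_train_records(plan, fold)
  tr_idx <- which(meta$record_id %in% tr$record_id)
  te_idx <- which(meta$record_id %in% te$record_id)
  test_subjects <- plan$folds$subject_id[plan$folds$fold == fold]
  if (any(meta$subject_id[tr_idx] %in% test_subjects)) {
    stop("protocol violation: training rows from test-fold subjects")
  }
  lab <- meta$label
  id_mask <- lab != ood_label()
  scaler <- fit_scaler(ctx$F_eng, tr_idx)
  sc <- function(X) if (cfg$standardize) apply_scaler(X, scaler) else X
  list(te = te, tr_idx = tr_idx, te_idx = te_idx,
       tr_id = tr_idx[id_mask[tr_idx]], te_id = te_idx[id_mask[te_idx]],
       test_subjects = test_subjects, id_mask = id_mask, lab = lab,
       scaler = scaler, sc = sc,
       Feng = feature_values(sc(ctx$F_eng)),
       Peng_tr = feature_values(sc(ctx$F_proxy_train)),
       Peng_ev = feature_values(sc(ctx$F_proxy_eval)))
}

# Per-grouping feature/model bundle ("fx") for one fold.
build_fold_features <- function(fold, ctx, cfg, grouping, fc) {
  lab_g <- ifelse(fc$id_mask, NA, ood_label())
  lab_g[fc$id_mask] <- apply_grouping(fc$lab[fc$id_mask], grouping)
  fx <- list(tr_idx = fc$tr_idx, tr_id = fc$tr_id, lab_g = lab_g,
             feats = list(eng = fc$Feng, emb = NULL),
             proxy_train = list(eng = fc$Peng_tr, emb = NULL),
             proxy_eval = list(eng = fc$Peng_ev, emb = NULL),
             fcn_id = NULL, fcn_proxy = NULL, emb_transform = NULL,
             softmax_scores = NULL, proxy_fcn_scores = NULL)
  if (needs_fcn(cfg)) {
    sub <- subsample_idx(fc$tr_id, cfg$max_fcn_train,
                         stage_seed(cfg$seed, paste0("fcnsub", fold, grouping)))
    fcn_cfg <- cfg$fcn
    fcn_cfg$seed <- stage_seed(cfg$seed, paste0("fcn", fold, grouping))
    fx$fcn_id <- fit_fcn(ws_subset(ctx$pre$clinic, sub), lab_g[sub], fcn_cfg)
    outs <- fcn_outputs(fx$fcn_id, ctx$pre$clinic)
    src <- outs$embedding[fc$tr_idx, , drop = FALSE]
    ectr <- colMeans(src)
    esd <- sqrt(colMeans(sweep(src, 2L, ectr)^2))
    esd[esd == 0] <- Inf
    fx$emb_transform <- function(E) sweep(sweep(E, 2L, ectr), 2L, esd, "/")
    fx$feats$emb <- fx$emb_transform(outs$embedding)
    fx$proxy_train$emb <- fx$emb_transform(
      fcn_embeddings(fx$fcn_id, ctx$pre$proxy_train))
    fx$proxy_eval$emb <- fx$emb_transform(
      fcn_embeddings(fx$fcn_id, ctx$pre$proxy_eval))
    fx$softmax_scores <- 1 - apply(outs$proba, 1L, max)
    if ("proxy_fcn" %in% cfg$detectors) {
      n_match <- min(n_windows(ctx$pre$proxy_train), length(sub))
      psub <- subsample_idx(seq_len(n_windows(ctx$pre$proxy_train)), n_match,
                            stage_seed(cfg$seed, paste0("pxsub", fold, grouping)))
      ws_tr <- bind_window_sets(ws_subset(ctx$pre$clinic, sub),
                                ws_subset(ctx$pre$proxy_train, psub))
      pf_cfg <- fcn_cfg
      pf_cfg$seed <- stage_seed(cfg$seed, paste0("pfcn", fold, grouping))
      fx$fcn_proxy <- fit_fcn(ws_tr, c(lab_g[sub], rep(ood_label(), length(psub))),
                              pf_cfg)
      fx$proxy_fcn_scores <- as.numeric(
        predict_proba(fx$fcn_proxy, ctx$pre$clinic)[, ood_label()])
    }
  }
  fx
}

run_fold <- function(fold, ctx, cfg) {
  fc <- build_fold_context(fold, ctx, cfg)
  te <- fc$te
  tr_idx <- fc$tr_idx
  tr_id <- fc$tr_id
  te_id <- fc$te_id
  test_subjects <- fc$test_subjects

  results <- list()
  emit <- function(method, task, grouping, metric, value) {
    results[[length(results) + 1L]] <<- tibble::tibble(
      method = method, task = task, grouping = grouping, fold = fold,
      metric = metric, value = value)
  }

  for (grouping in cfg$groupings) {
    fx <- build_fold_features(fold, ctx, cfg, grouping, fc)
    lab_g <- fx$lab_g

    # ---- pooled detectors: fit once, evaluate in-clinic ----
    pooled <- setdiff(cfg$detectors, grep("patient_knn", cfg$detectors, value = TRUE))
    dets <- list()
    proxy_data <- list(eng = fc$Peng_ev, emb = fx$proxy_eval$emb,
                       ws = ctx$pre$proxy_eval)
    for (kind in pooled) {
      res <- tryCatch({
        det <- fit_fold_detector(kind, fx, cfg, fold, grouping)
        dets[[kind]] <- det
        s_te <- if (det$kind %in% c("softmax", "proxy_fcn")) {
          (if (det$kind == "softmax") fx$softmax_scores else fx$proxy_fcn_scores)[te_id]
        } else {
          ood_scores(det, fx$feats[[feat_of(kind)]][te_id, , drop = FALSE])
        }
        s_px <- detector_scores_on(det, kind, proxy_data)
        score_eval(c(s_te, s_px),
                   c(rep(TRUE, length(s_te)), rep(FALSE, length(s_px))),
                   det$threshold)
      }, error = function(e) {
        warning("detector ", kind, " failed in fold ", fold, ": ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(res)) {
        for (m in names(res)) emit(kind, "ood_clinic", grouping, m, res[[m]])
      }
    }

    # ---- patient-specific detectors / classifiers ----
    patient_specific_fold(fold, ctx, cfg, fx, grouping, te, emit)

    # ---- pooled classifiers ----
    truth_g <- lab_g[te_id]
    pooled_cls <- setdiff(cfg$classifiers,
                          c("patient_knn_engineered", "patient_knn_embedding"))
    for (kind in pooled_cls) {
      feat <- feat_of(kind)
      pred <- tryCatch(switch(sub("_(engineered|embedding)$", "", kind),
        rf = {
          rf <- fit_random_forest(fx$feats[[feat]][tr_id, , drop = FALSE],
                                  lab_g[tr_id],
                                  seed = stage_seed(cfg$seed,
                                                    paste0("rf", kind, fold, grouping)))
          predict(rf, fx$feats[[feat]][te_id, , drop = FALSE])
        },
        fcn = predict(fx$fcn_id, ws_subset(ctx$pre$clinic, te_id))
      ), error = function(e) {
        warning("classifier ", kind, " failed in fold ", fold, ": ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(pred)) {
        emit(kind, "classify", grouping, "accuracy", mean(pred == truth_g))
        if (grouping == "exercise") {
          for (lv in setdiff(grouping_levels(), "exercise")) {
            assert_coarsening(pred, truth_g, lv)
          }
        }
      }
    }

    # ---- at-home evaluation on the fold's test subjects ----
    if (cfg$eval_home && length(ctx$pre$home) > 0L) {
      home_eval_fold(ctx, cfg, fx, dets, grouping, test_subjects, fc$sc, emit)
    }
  }
  dplyr::bind_rows(results)
}

patient_specific_fold <- function(fold, ctx, cfg, fx, grouping, te, emit) {
  det_kinds <- intersect(cfg$detectors,
                         c("patient_knn_engineered", "patient_knn_embedding",
                           "proxy_patient_knn_engineered",
                           "proxy_patient_knn_embedding"))
  cls_kinds <- intersect(cfg$classifiers,
                         c("patient_knn_engineered", "patient_knn_embedding"))
  if (length(det_kinds) == 0L && length(cls_kinds) == 0L) return(invisible(NULL))
  meta <- ctx$pre$clinic$meta
  plan <- ctx$plan
  acc <- list()
  for (s in unique(te$subject_id)) {
    sup_rec <- plan$support_records$record_id[plan$support_records$subject_id == s]
    sup_idx <- which(meta$record_id %in% sup_rec & meta$label != ood_label())
    s_te_idx <- which(meta$record_id %in% te$record_id[te$subject_id == s] &
                        meta$label != ood_label())
    if (length(sup_idx) == 0L || length(s_te_idx) == 0L) next
    for (kind in det_kinds) {
      feat <- feat_of(kind)
      if (is.null(fx$feats[[feat]])) next
      S <- fx$feats[[feat]][sup_idx, , drop = FALSE]
      Q <- rbind(fx$feats[[feat]][s_te_idx, , drop = FALSE],
                 fx$proxy_eval[[feat]])
      positive <- c(rep(TRUE, length(s_te_idx)), rep(FALSE, nrow(fx$proxy_eval[[feat]])))
      det <- if (grepl("^proxy", kind)) {
        n_match <- min(nrow(fx$proxy_train[[feat]]), nrow(S))
        psub <- subsample_idx(seq_len(nrow(fx$proxy_train[[feat]])), n_match,
                              stage_seed(cfg$seed, paste0("ppx", fold, s)))
        fit_proxy_detector(rbind(S, fx$proxy_train[[feat]][psub, , drop = FALSE]),
                           c(fx$lab_g[sup_idx], rep(ood_label(), length(psub))),
                           base = "patient_knn")
      } else {
        suppressWarnings(fit_patient_knn_detector(S, k = 3L))
      }
      det <- suppressWarnings(
        calibrate_detector(det, sensitivity_target = cfg$sensitivity_target,
                           loo = TRUE))
      a <- acc[[kind]] %||% list(scores = NULL, positive = NULL, keep = NULL)
      sc_ <- ood_scores(det, Q)
      acc[[kind]] <- list(scores = c(a$scores, sc_),
                          positive = c(a$positive, positive),
                          keep = c(a$keep, sc_ <= det$threshold))
    }
    for (kind in cls_kinds) {
      feat <- feat_of(kind)
      if (is.null(fx$feats[[feat]])) next
      key <- paste0("cls_", kind)
      pred <- patient_knn_classify(fx$feats[[feat]][sup_idx, , drop = FALSE],
                                   fx$feats[[feat]][s_te_idx, , drop = FALSE],
                                   fx$lab_g[sup_idx], k = 3L)
      a <- acc[[key]] %||% list(pred = NULL, truth = NULL)
      acc[[key]] <- list(pred = c(a$pred, pred),
                         truth = c(a$truth, fx$lab_g[s_te_idx]))
    }
  }
  for (kind in det_kinds) {
    a <- acc[[kind]]
    if (is.null(a) || !any(a$positive) || !all(c(TRUE, FALSE) %in% a$positive)) next
    bm <- binary_metrics(a$keep, a$positive)
    emit(kind, "ood_clinic", grouping, "auroc", auroc(-a$scores, a$positive))
    emit(kind, "ood_clinic", grouping, "f1", bm$f1)
    emit(kind, "ood_clinic", grouping, "sensitivity", bm$sensitivity)
    emit(kind, "ood_clinic", grouping, "specificity", bm$specificity)
  }
  for (kind in cls_kinds) {
    a <- acc[[paste0("cls_", kind)]]
    if (is.null(a) || length(a$pred) == 0L) next
    emit(kind, "classify", grouping, "accuracy", mean(a$pred == a$truth))
    if (grouping == "exercise") {
      for (lv in setdiff(grouping_levels(), "exercise")) {
        assert_coarsening(a$pred, a$truth, lv)
      }
    }
  }
  invisible(NULL)
}

home_eval_fold <- function(ctx, cfg, fx, dets, grouping, test_subjects, sc, emit) {
  meta <- ctx$pre$clinic$meta
  plan <- ctx$plan
  pknn_eng <- "patient_knn_engineered" %in% cfg$detectors
  rows <- list()
  for (hw in ctx$pre$home) {
    subj <- hw$meta$subject_id[1L]
    if (!subj %in% test_subjects) next
    truth <- hw$meta$label != ood_label()
    data <- list(eng = feature_values(sc(extract_features(hw))), emb = NULL,
                 ws = hw)
    if (!is.null(fx$emb_transform)) {
      data$emb <- fx$emb_transform(fcn_embeddings(fx$fcn_id, hw))
    }
    for (kind in names(dets)) {
      if (feat_of(kind) == "emb" && is.null(data$emb)) next
      s <- detector_scores_on(dets[[kind]], kind, data)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        evaluate_record(s, s <= dets[[kind]]$threshold, truth,
                        hw$meta$record_id[1L]),
        method = kind)
    }
    if (pknn_eng) {
      sup_rec <- plan$support_records$record_id[plan$support_records$subject_id == subj]
      sup_idx <- which(meta$record_id %in% sup_rec & meta$label != ood_label())
      if (length(sup_idx) > 0L) {
        det <- suppressWarnings(
          fit_patient_knn_detector(fx$feats$eng[sup_idx, , drop = FALSE], k = 3L))
        det <- suppressWarnings(
          calibrate_detector(det, sensitivity_target = cfg$sensitivity_target,
                             loo = TRUE))
        s <- ood_scores(det, data$eng)
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          evaluate_record(s, s <= det$threshold, truth, hw$meta$record_id[1L]),
          method = "patient_knn_engineered")
      }
    }
  }
  if (length(rows) == 0L) return(invisible(NULL))
  per_rec <- dplyr::bind_rows(rows)
  agg <- dplyr::summarise(
    dplyr::group_by(per_rec, .data$method),
    auroc = mean(.data$auroc, na.rm = TRUE), f1 = mean(.data$f1, na.rm = TRUE),
    sensitivity = mean(.data$sensitivity, na.rm = TRUE),
    specificity = mean(.data$specificity, na.rm = TRUE), .groups = "drop")
  for (i in seq_len(nrow(agg))) {
    for (m in c("auroc", "f1", "sensitivity", "specificity")) {
      if (!is.nan(agg[[m]][i])) {
        emit(agg$method[i], "ood_home", grouping, m, agg[[m]][i])
      }
    }
  }
  invisible(NULL)
}

#' Run an experiment grid on a cohort
#'
#' Executes the full protocol: preprocessing, subject-wise CV planning with
#' the support-exclusion rule, per-fold feature extraction (and FCN training
#' where a method requires it), detector fitting with
#' sensitivity-constrained calibration on training-split exercise windows,
#' in-clinic OOD evaluation (test-session exercise windows as positives,
#' held-out proxy-subject windows as negatives), in-distribution
#' classification accuracy, patient-specific methods built on each test
#' subject's own support session, and per-record at-home evaluation against
#' the generator's ground-truth masks. A failing method is warned about and
#' skipped; the rest of the grid still runs.
#'
#' @param cohort A `synthetic_cohort`.
#' @param cfg An [experiment_config()].
#' @param out_dir Optional directory for `results.csv`, `summary.csv`,
#'   `config.lock.yaml` and `run.log`.
#' @return List: `results` (long tibble: method, task, grouping, fold,
#'   metric, value), `summary` (fold means and standard errors), `plan`,
#'   `config_hash`, `runtime_s`.
#' @export
run_experiment <- function(cohort, cfg = experiment_config(), out_dir = NULL) {
  t0 <- Sys.time()
  pre <- preprocess_cohort(cohort, cfg$preprocess)
  plan <- make_cv_plan(cohort$manifest, cfg$n_folds,
                       seed = stage_seed(cfg$seed, "cvplan"))

  # proxy subjects split in half: first half trains proxy methods, second
  # half provides the evaluation negatives (no shared proxy subject)
  px_subjects <- sort(unique(pre$proxy$meta$subject_id))
  n_tr <- max(1L, floor(length(px_subjects) / 2))
  px_tr <- px_subjects[seq_len(n_tr)]
  proxy_train <- ws_subset(pre$proxy, pre$proxy$meta$subject_id %in% px_tr)
  proxy_eval <- ws_subset(pre$proxy, !pre$proxy$meta$subject_id %in% px_tr)

  ctx <- list(
    plan = plan,
    pre = list(clinic = pre$clinic, home = pre$home,
               proxy_train = proxy_train, proxy_eval = proxy_eval),
    F_eng = extract_features(pre$clinic),
    F_proxy_train = extract_features(proxy_train),
    F_proxy_eval = extract_features(proxy_eval)
  )

  folds <- cfg$folds %||% seq_len(cfg$n_folds)
  results <- dplyr::bind_rows(lapply(folds, run_fold, ctx = ctx, cfg = cfg))
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$method, .data$task, .data$grouping,
                    .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    n_folds = sum(!is.na(.data$value)), .groups = "drop")
  hash <- rlang::hash(cfg)
  out <- list(results = results, summary = summary, plan = plan,
              config_hash = hash,
              runtime_s = as.numeric(Sys.time() - t0, units = "secs"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    yaml::write_yaml(list(config_hash = hash, seed = cfg$seed,
                          detectors = cfg$detectors, classifiers = cfg$classifiers,
                          groupings = cfg$groupings, n_folds = cfg$n_folds),
                     file.path(out_dir, "config.lock.yaml"))
    writeLines(sprintf("[%s] experiment done: %d result rows, %.1f s, hash %s",
                       format(Sys.time()), nrow(results), out$runtime_s, hash),
               file.path(out_dir, "run.log"))
  }
  out
}

#' Audit threshold calibration for every detector family
#'
#' Fits each requested detector family on one fold's training split of a
#' cohort, runs the sensitivity-constrained calibration exactly as
#' [run_experiment()] does (training-split exercise windows for pooled
#' detectors; leave-one-out support scores for patient-specific ones;
#' out-of-bag scores for the proxy random forest), then *recomputes* the
#' fraction of calibration exercise scores at or below each selected
#' threshold.
#'
#' @param cohort A `synthetic_cohort`.
#' @param cfg An [experiment_config()]; its `detectors` define the families
#'   audited and `groupings[1]` the grouping level used.
#' @param fold Fold whose training split is used.
#' @return Tibble: `kind`, `threshold`, `achieved_sensitivity`, `n_scores`.
#' @export
calibration_audit <- function(cohort, cfg = experiment_config(), fold = 1L) {
  pre <- preprocess_cohort(cohort, cfg$preprocess)
  plan <- make_cv_plan(cohort$manifest, cfg$n_folds,
                       seed = stage_seed(cfg$seed, "cvplan"))
  px_subjects <- sort(unique(pre$proxy$meta$subject_id))
  n_tr <- max(1L, floor(length(px_subjects) / 2))
  px_tr <- px_subjects[seq_len(n_tr)]
  ctx <- list(
    plan = plan,
    pre = list(clinic = pre$clinic, home = pre$home,
               proxy_train = ws_subset(pre$proxy, pre$proxy$meta$subject_id %in% px_tr),
               proxy_eval = ws_subset(pre$proxy, !pre$proxy$meta$subject_id %in% px_tr)),
    F_eng = extract_features(pre$clinic),
    F_proxy_train = extract_features(ws_subset(pre$proxy,
                                               pre$proxy$meta$subject_id %in% px_tr)),
    F_proxy_eval = extract_features(ws_subset(pre$proxy,
                                              !pre$proxy$meta$subject_id %in% px_tr))
  )
  grouping <- cfg$groupings[1L]
  fc <- build_fold_context(fold, ctx, cfg)
  fx <- build_fold_features(fold, ctx, cfg, grouping, fc)
  meta <- ctx$pre$clinic$meta

  rows <- list()
  pooled <- setdiff(cfg$detectors, grep("patient_knn", cfg$detectors, value = TRUE))
  for (kind in pooled) {
    det <- fit_fold_detector(kind, fx, cfg, fold, grouping)
    # independent recomputation of the achieved calibration sensitivity
    cal_scores <- switch(det$kind,
      softmax = fx$softmax_scores[fx$tr_id],
      proxy_fcn = fx$proxy_fcn_scores[fx$tr_id],
      proxy_rf = det$oob_ood[det$train_labels != ood_label()],
      ood_scores(det, fx$feats[[feat_of(kind)]][fx$tr_id, , drop = FALSE])
    )
    rows[[kind]] <- tibble::tibble(
      kind = kind, threshold = det$threshold,
      achieved_sensitivity = mean(cal_scores <= det$threshold),
      n_scores = length(cal_scores))
  }
  pknn <- intersect(cfg$detectors,
                    c("patient_knn_engineered", "patient_knn_embedding",
                      "proxy_patient_knn_engineered", "proxy_patient_knn_embedding"))
  if (length(pknn) > 0L) {
    subjects <- unique(fc$te$subject_id)
    for (kind in pknn) {
      feat <- feat_of(kind)
      hits <- total <- 0L
      taus <- numeric()
      for (s in subjects) {
        sup_rec <- plan$support_records$record_id[plan$support_records$subject_id == s]
        sup_idx <- which(meta$record_id %in% sup_rec & meta$label != ood_label())
        if (length(sup_idx) == 0L) next
        S <- fx$feats[[feat]][sup_idx, , drop = FALSE]
        det <- if (grepl("^proxy", kind)) {
          n_match <- min(nrow(fx$proxy_train[[feat]]), nrow(S))
          psub <- subsample_idx(seq_len(nrow(fx$proxy_train[[feat]])), n_match,
                                stage_seed(cfg$seed, paste0("ppx", fold, s)))
          fit_proxy_detector(rbind(S, fx$proxy_train[[feat]][psub, , drop = FALSE]),
                             c(fx$lab_g[sup_idx], rep(ood_label(), length(psub))),
                             base = "patient_knn")
        } else {
          suppressWarnings(fit_patient_knn_detector(S, k = 3L))
        }
        det <- suppressWarnings(
          calibrate_detector(det, sensitivity_target = cfg$sensitivity_target,
                             loo = TRUE))
        cal <- loo_support_scores(det)
        hits <- hits + sum(cal <= det$threshold)
        total <- total + length(cal)
        taus <- c(taus, det$threshold)
      }
      if (total > 0L) {
        rows[[kind]] <- tibble::tibble(
          kind = kind, threshold = stats::median(taus),
          achieved_sensitivity = hits / total, n_scores = total)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Canonical benchmark configurations
#'
#' The fixed method grids the package uses to characterize itself on the
#' default [benchmark_cohort()]: `benchmark_experiment_config()` runs the
#' five-fold protocol with the engineered-feature detectors the synthetic
#' recovery checks are stated on, and `benchmark_audit_config()` names every
#' detector family for the calibration audit, with reduced FCN epochs and a
#' capped FCN training subsample so the audit stays desk-scale.
#'
#' @param seed Experiment seed.
#' @return An [experiment_config()].
#' @export
benchmark_experiment_config <- function(seed = 0L) {
  experiment_config(
    detectors = c("kmeans_engineered", "proxy_rf_engineered"),
    classifiers = "rf_engineered",
    groupings = c("exercise", "simple_motion"),
    n_folds = 5L, eval_home = FALSE, seed = seed)
}

#' @rdname benchmark_experiment_config
#' @export
benchmark_audit_config <- function(seed = 0L) {
  experiment_config(
    detectors = DETECTOR_KINDS,
    classifiers = "rf_engineered",
    groupings = "simple_motion",
    n_folds = 5L, fcn = fcn_config(epochs = 6L), max_fcn_train = 500L,
    eval_home = FALSE, seed = seed)
}
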