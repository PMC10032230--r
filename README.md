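# rehabsense

Detection and classification of shoulder physiotherapy exercise from
wrist-worn inertial sensors.

## The problem

Rotator-cuff rehabilitation depends on home exercise programmes, but
adherence to them is essentially unmeasured: diaries under-report, and a
smartwatch on the affected wrist records far more non-exercise than exercise.
`rehabsense` implements a two-stage machine-learning pipeline for exactly
this setting:

1. **Out-of-distribution (OOD) removal.** Every ten-second window of 6-channel
   inertial data (3-axis accelerometer with gravity, 3-axis gyroscope, 50 Hz)
   receives an OOD score — higher means less exercise-like. A threshold
   calibrated under a minimum-sensitivity constraint (sensitivity ≥ 0.90 on
   calibration exercise windows, so prescribed exercise is rarely discarded)
   removes rest and activities of daily living.
2. **Exercise classification.** Retained windows are labelled with one of 18
   rotator-cuff exercises, or a coarser motion grouping (motion, simple
   motion, optionally combined with body position), by a random forest, a
   fully convolutional network (FCN), or a patient-specific k-nearest-neighbour
   model fitted on the patient's own most recent supervised session.

Detector families: KMeans centroid distance, FCN softmax confidence,
patient-specific KNN distance (k = 3, Euclidean), and proxy-supervised
variants that add an external ADL dataset as an explicit extra class —
each over 60 engineered statistics per window (median, RMS, SD, variance,
min, max, skewness, kurtosis, mean spectral energy, mean crossings × 6
channels) or over the FCN's 128-wide penultimate-layer embedding. Evaluation
is subject-wise five-fold cross-validation with session-aware test/support
splits and a support-exclusion rule, reporting AUROC, F1, sensitivity and
specificity as fold means with standard errors.

Because the clinical data this pipeline targets cannot ship with the
package, `rehabsense` includes a fully seeded synthetic cohort generator —
quasi-periodic exercise bouts with right-skewed repetition periods (mean
3.8 s, SD 2.3 s), per-subject and per-session technique variation, at-home
records with exact ground-truth masks, and a deliberately mismatched proxy
ADL dataset — so the complete pipeline is reproducible end to end. The FCN
(three conv blocks 128/256/128 with batch norm and ReLU, global average
pooling, Adam, cross-entropy) is implemented in the package with
BLAS-backed compiled kernels; no deep-learning framework is required.

## A worked example

```r
library(rehabsense)

# a small synthetic cohort: 6 subjects, 2 supervised sessions each,
# one at-home record per subject, 2 held-out proxy ADL subjects
cohort <- simulate_cohort(cohort_config(
  n_subjects = 6, n_sessions = 2, home_duration = 120,
  n_proxy_subjects = 2, proxy_duration = 120, seed = 5))

cfg <- experiment_config(
  detectors   = c("kmeans_engineered", "patient_knn_engineered",
                  "proxy_rf_engineered"),
  classifiers = "rf_engineered",
  groupings   = "simple_motion",
  n_folds     = 3, eval_home = FALSE, seed = 11)

res <- run_experiment(cohort, cfg)
print(res$summary, n = 13)
```

```
# A tibble: 13 × 7
   method                 task       grouping      metric   mean      se n_folds
   <chr>                  <chr>      <chr>         <chr>   <dbl>   <dbl>   <int>
 1 kmeans_engineered      ood_clinic simple_motion auroc   0.936 0.0458        3
 2 kmeans_engineered      ood_clinic simple_motion f1      0.752 0.0711        3
 3 kmeans_engineered      ood_clinic simple_motion sensit… 0.612 0.0876        3
 4 kmeans_engineered      ood_clinic simple_motion specif… 1     0             3
 5 patient_knn_engineered ood_clinic simple_motion auroc   0.992 0.00504       3
 6 patient_knn_engineered ood_clinic simple_motion f1      0.802 0.0699        3
 7 patient_knn_engineered ood_clinic simple_motion sensit… 0.681 0.101         3
 8 patient_knn_engineered ood_clinic simple_motion specif… 1     0             3
 9 proxy_rf_engineered    ood_clinic simple_motion auroc   0.998 0.00125       3
10 proxy_rf_engineered    ood_clinic simple_motion f1      0.535 0.117         3
11 proxy_rf_engineered    ood_clinic simple_motion sensit… 0.383 0.113         3
12 proxy_rf_engineered    ood_clinic simple_motion specif… 1     0             3
13 rf_engineered          classify   simple_motion accura… 0.912 0.0489        3
```

Reading the output: each row is a fold-mean with its standard error. The
`ood_clinic` task scores each method at separating the test subjects'
exercise windows (positives) from held-out proxy ADL windows (negatives);
the patient-specific KNN (AUROC 0.992) and the proxy-trained random forest
(0.998) clearly beat unsupervised KMeans distance (0.936), the ordering this
method family is known for. Sensitivities sit well below the 0.90 achieved
on the calibration split — the cohort's inter-subject technique variation
shifts scores upward on unseen subjects, which is precisely the fixed-threshold
behaviour the pipeline must cope with. The `classify` row reports
held-out simple-motion accuracy of the random forest (0.912 on this small
cohort).

The same objects compose manually: `preprocess_record()` →
`extract_features()` → `fit_patient_knn_detector()` → `calibrate_detector()`
→ `detect()` all take and return tibbles or tibble-carrying containers, and
fitted models have `tidy()`/`glance()` methods and `autoplot()`s.

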