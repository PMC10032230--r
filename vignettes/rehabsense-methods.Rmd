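---
title: "Methods: two-stage detection and classification of shoulder physiotherapy exercise from wrist-worn inertial data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage detection and classification of shoulder physiotherapy exercise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients rehabilitating rotator-cuff injuries are prescribed home exercise
programmes, and adherence to those programmes is hard to measure objectively.
A smartwatch worn on the affected arm records 3-axis accelerometer (m/s², raw
convention, gravity included) and 3-axis gyroscope (rad/s) streams whenever
the patient wears it — during supervised weekly clinic sessions, where a
physiotherapist labels each exercise set in real time, and at home, where
nothing is labelled and most of the recording is not exercise at all.

Turning such a stream into an adherence measure requires two decisions per
ten-second window of data:

1. **Is this exercise at all?** Out-of-distribution (OOD) detection removes
   rest and activities of daily living (ADL).
2. **Which exercise is it?** In-distribution classification labels the
   retained windows with one of 18 rotator-cuff exercises, or a coarser
   motion grouping.

`rehabsense` implements this two-stage pipeline end to end, together with a
seeded synthetic cohort generator that emulates the statistical structure the
pipeline assumes, so every component can be exercised and evaluated without
clinical data.

## Preprocessing

The watch samples its sensors asynchronously at roughly 50 Hz. Streams are
linearly interpolated per channel onto a uniform 50 Hz grid anchored at the
record's first sample, with no extrapolation beyond the recorded support.
Linear interpolation is the minimal-assumption choice and is directly
testable against analytic signals (a jittered sine is reconstructed to well
under 1% of its amplitude). If consecutive timestamps are more than one
second apart the watch evidently stopped streaming; the record is split at
the gap rather than interpolated across it, so no signal is fabricated over
sensor dropouts.

Uniform records are segmented with a **10 s window (500 samples) advancing
50 samples (1 s)** per step — 90% overlap; the trailing partial window is
discarded, giving `floor((N − 500)/50) + 1` windows per record. A window
takes the class covering strictly more than half of its samples under the
record's label mask (half-open `[t_start, t_end)` intervals); windows with no
strict majority — including exact ties — are labelled with the reserved OOD
label. The majority fraction is a package decision exposed in
`preprocess_config()`.

## Features

Two feature families feed the models, interchangeable behind one tabular
container:

* **Engineered statistics** — per channel per window: median, root mean
  square, population SD and variance, min, max, moment-based skewness
  (`m3/m2^1.5`) and excess kurtosis (`m4/m2² − 3`, both 0 for a constant
  channel so degenerate windows never produce NaN), mean spectral energy
  (mean over all 500 DFT bins of the squared magnitude, computed via
  Parseval's identity as `L·mean(x²)`; tests verify it against an explicit
  FFT), and mean crossings (consecutive samples strictly on opposite sides
  of the channel mean — a sample exactly at the mean is not a crossing,
  keeping the count deterministic on integer-valued signals). 6 channels ×
  10 statistics = 60 features.
* **Learned embeddings** — the global-average-pooled, pre-softmax activation
  of the fully convolutional network (128-wide), extracted by a feature
  extractor fitted on the training split only.

Because KMeans and k-nearest-neighbour methods compare features with a
Euclidean metric, features are z-scored per column with statistics from the
**training rows only** (population SD; zero-variance columns map to 0). Tree
models are invariant to this affine map, so the same standardized matrix
feeds every model; the switch is `experiment_config(standardize = )`.

## The fully convolutional network

The FCN is the standard time-series architecture: three 1-D convolution
blocks of (128 filters, kernel 8), (256, 5), (128, 3), each followed by batch
normalization and ReLU; global average pooling over time; one linear layer to
the class count with softmax. Training uses Adam at learning rate 1e-4 with
cross-entropy; the reference setting is batch 256 for 150 epochs, and the
epoch count is configuration-scaled everywhere the package trains at desk
scale (tests use 10 epochs on toy windows; the benchmark audit uses 6).

Implementation choices worth knowing:

* The network is implemented in this package directly: convolutions run as
  sums of offset BLAS `dgemm` calls on the flat `(batch·time) × channels`
  activation matrix, and the batch-norm/ReLU passes are small compiled
  kernels. Gradients are verified against central finite differences in the
  test suite's development history; predictions are deterministic given the
  configuration seed.
* Within each optimizer batch, batch-norm statistics are computed on
  sub-batches of `ghost_size` windows (default 64, "ghost batch norm"),
  which bounds peak memory at the 500-sample window length; running averages
  of those statistics (momentum 0.9) are used at inference.
* Inputs are z-normalized per channel with training-split statistics.
* The "embedding" is the pooled pre-softmax activation, so its width (128)
  does not depend on the class count, and applying the stored linear layer
  to an embedding reproduces the softmax probabilities exactly — an
  internal-consistency identity the tests assert.

## OOD detectors and threshold calibration

All detectors share one convention: **the score is OOD-ness** (higher = more
likely non-exercise) and a window is kept as exercise iff
`score ≤ τ`. Five families are implemented, each over engineered features or
FCN embeddings where applicable:

| family | score |
|---|---|
| KMeans | Euclidean distance to the nearest of `k` centroids fitted on in-distribution training features (`k` = class count under the active grouping, following the observation that regrouping moves cluster centres) |
| softmax | `1 − max` class probability of an FCN trained on exercise classes only |
| patient-specific KNN | mean Euclidean distance to the 3 nearest windows of the patient's own support session |
| proxy RF / proxy FCN | predicted probability of an explicit proxy non-exercise class added to supervised training (proxy rows size-matched to the in-distribution rows by seeded subsampling) |
| proxy patient-KNN | fraction of the 3 nearest support rows that are proxy |

Thresholds are selected under a **minimum-sensitivity constraint of 0.90**:
`τ` is the smallest observed calibration score such that at least 90% of
calibration exercise scores lie at or below it — the most specific threshold
that still guarantees the target sensitivity on the calibration set, so
exercise is rarely discarded (missing exercise is the costlier error for
adherence tracking).

Which data calibrate the threshold is a package decision (and flagged as
such): the labelled exercise windows of the **training split**, never the
test subject's sessions. Two refinements avoid degenerate optimism:

* patient-specific detectors calibrate on their own support session via
  leave-one-out scoring (each support window scored against the others),
  since a window's distance to itself is zero;
* the proxy random forest calibrates on its out-of-bag OOD vote fractions,
  since resubstitution scores of a forest sit near zero for every training
  row and would select a meaninglessly small threshold.

The calibration guarantee — achieved sensitivity on the calibration windows
at or above the target, for every family — holds by construction of the
selection rule and is re-verified on the benchmark cohort by
`calibration_audit()`. Sensitivity on *held-out subjects* is lower (the
synthetic cohort's inter-subject technique variation shifts scores upward),
which is exactly the behaviour a fixed threshold shows on new patients.

## Evaluation protocol

Subject-wise five-fold cross-validation: subjects are shuffled by seed and
partitioned evenly; **no window from a test-fold subject ever enters
training** (asserted on every materialized fold). Per test subject, the test
set is the most recent supervised session; the patient-specific support for
each class comes from the most recent *earlier* session containing that
class (normally the second-to-last session, with earlier-session
substitution when a class is missing there). Test records whose class never
appears in any earlier session of that subject are excluded — identically
for all methods, so every method sees the same test set; the plan records
each exclusion with its reason.

Because clinic data contain (almost) no labelled non-exercise, the in-clinic
OOD evaluation uses proxy ADL windows as negatives. The proxy subjects are
split in half: the first half trains proxy methods, the second half provides
the evaluation negatives, so no proxy subject appears on both sides.

Metrics: rank-based AUROC (ties 0.5; computed from the continuous scores,
not the thresholded mask), F1, sensitivity, specificity, accuracy; fold
means are reported with the standard error `sd/√n_folds`. At-home records
are evaluated per record against the generator's exact masks and averaged
within fold; records containing no true exercise contribute specificity
only. Coarsening is checked exactly on every evaluation run at the exercise
grouping: mapping exercise-level predictions to any coarser grouping can
never lower accuracy (a correct fine prediction stays correct), and the run
aborts if the identity is violated.

Grouping levels (exercise → motion / simple motion, optionally with body
position) are applied to the labels **before** fitting, so each grouped
result uses a classifier trained at that granularity.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults define the study
conditions the package characterizes itself under.

* **Repetition periods** are lognormal, moment-matched to mean 3.8 s and
  SD 2.3 s — the right-skewed, slow repetitions of a rotator-cuff patient
  population. The lognormal is the simplest positive right-skewed family
  consistent with those moments.
* **Class templates.** Every class shares a quasi-periodic motion backbone
  (three harmonics per channel); the class-separation parameter `sep` scales
  group- and class-level amplitude and phase deviations from that backbone,
  plus a gravity-orientation deviation. Classes in the same simple-motion
  group draw from a common group base, so within-group templates are
  measurably more similar than between-group ones — the structural reason
  grouping eases classification. At `sep = 0` all templates collapse onto
  one motion. A consequence worth noting: `sep` separates classes *from each
  other*; exercise-vs-ADL contrast is carried mostly by the backbone, so
  detector AUROC responds only weakly to `sep` while classification accuracy
  responds strongly (the property tests assert exactly that).
* **Subjects and sessions.** Each subject gets a prescription of 5 of the 8
  default classes, a technique profile (random device/limb rotation, SD
  0.32 rad; amplitude and speed scalings), and a smaller per-session drift
  (SD 0.08). Each session produces one short clinic record per performed
  exercise (prescribed exercises are performed with probability 0.9, so a
  test-session class occasionally lacks earlier-session support and the
  exclusion rule has something to do). Accelerometer output includes rotated
  gravity (9.81 m/s²), making device attitude a usable class cue as in real
  data.
* **Non-exercise.** ADL/rest segments are mean-reverting (exact-transition
  Ornstein–Uhlenbeck) motion under a slowly drifting gravity orientation,
  scaled by an intensity parameter with regime switching; intensity 0 is
  near-static rest. Home records interleave exercise bouts, rest (including
  one long 55–75 s near-static stretch per record) and ADL segments, with
  exact ground-truth masks. The proxy dataset comes from disjoint "proxy
  subjects" with a shifted intensity mixture, so the proxy is a deliberately
  imperfect stand-in for home OOD data, mirroring the relationship between
  an external ADL corpus and real at-home non-exercise.
* **Timestamps** are jittered by U(−4, 4) ms around the 50 Hz grid to
  exercise the resampler (the jitter cannot reorder samples).

What the generator does **not** emulate: biomechanics (no joint-angle
model), labelling noise, device-contact artefacts, missing-data corruption
within a record, or any attempt to imitate specific patients. Passing tests
therefore demonstrate the pipeline's correctness and its qualitative
behaviour under controlled distribution shift — not clinical-grade accuracy
on real patients.

## The benchmark cohort and problem sizes

The package's canonical benchmark is `benchmark_cohort()`: **12 subjects ×
3 supervised sessions × 8 classes** (one home record per subject, 4 proxy
subjects), fixed seed — about 2,700 clinic windows. This size gives at least
two subjects per CV fold and two supervised sessions before each test
session while keeping every end-to-end check, including the all-family
calibration audit with its two FCN fits (6 epochs on a 500-window training
subsample), comfortably runnable on a single CPU. The audit and the
five-fold recovery run are exposed as `benchmark_audit_config()` and
`benchmark_experiment_config()` so the reported numbers are reproducible
verbatim.

On this benchmark the package reproduces the orderings the method family is
known for: proxy-supervised detection outperforms unsupervised KMeans
distance; simple-motion grouping outperforms exercise-level classification;
and a patient-specific KNN beats the pooled random forest when inter-subject
variability is large relative to class separation (asserted as a property
test at `subject_sd = 0.9`, `sep = 0.35`).

## Numerical and degenerate-input conventions

* Skewness/kurtosis of a constant channel are 0, never NaN.
* KNN majority ties break to the single nearest neighbour's class;
  distance-rank ties break by stable order.
* `calibrate_threshold()` on an all-equal score vector returns that value
  (achieved sensitivity 1).
* AUROC requires both classes; exercise-free records report specificity
  only.
* Empty window sets (records shorter than one window) warn and propagate as
  empty, never error, so one short record cannot abort a cohort run.
* All randomness flows from explicit seeds; per-stage seeds derive from the
  global seed via a hash of the stage name, so adding a stage never shifts
  another stage's stream.

## Known limitations

* The FCN at desk-scale epoch counts is a functioning but under-trained
  model; its embeddings and softmax scores are meaningful for protocol and
  calibration checks, not a statement about achievable deep-feature quality.
* In-clinic OOD negatives are proxy windows by necessity (clinic records are
  continuously supervised), so in-clinic specificity describes
  exercise-vs-proxy separation, not exercise-vs-home-life.
* The at-home evaluation covers the detector stage; home exercise-class
  accuracy is not evaluated, as home records' class composition mirrors the
  prescription rather than a balanced design.
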