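---
title: "Subject-aware evaluation of wearable fall-detection classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-aware evaluation of wearable fall-detection classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wearable fall-detection systems discriminate falls from activities of
daily living (ADLs) using the signals of a body-worn tri-axial
accelerometer, almost always through a supervised classifier trained on
movements executed by a panel of volunteers. The panel is rarely the
target population: detectors meant for older adults are trained on young,
healthy subjects, and most published evaluations even reuse the *same*
subjects for training and testing ("record-wise" evaluation), which is
known to inflate performance estimates.

`fallsense` provides the machinery to quantify two questions on any
waist-worn accelerometer dataset:

1. Does a classifier degrade when the training and test subjects differ in
   a physical characteristic — weight, height, body-mass index (BMI), age
   or sex?
2. Does it degrade when the *typology of movements* differs — when an
   entire category of ADLs is absent from training?

The package ships a synthetic dataset generator so that the full pipeline
is testable end to end without downloading any public repository; adapters
for real CSV-based repositories only need to produce the package's
manifest layout.

## Data model

A dataset is three tables plus one signal per trial:

* `subjects.csv` — `subject_id`, `sex` (female/male), `age`, `height_cm`,
  `weight_kg`, and the derived `bmi` = weight / (height in m)².
* `activities.csv` — `code`, `description`, `klass` (ADL/FALL) and
  `category`. ADLs belong to exactly one of four sub-categories graded by
  physical effort: `basic` (standing, sitting down, elementary gestures),
  `standard` (walking, stairs), `sporting` (running, jumping) and
  `near_fall` (trips and slips with recovery); falls form their own
  `fall` category, and `klass == "FALL"` exactly when
  `category == "fall"`.
* `trials.csv` — `trial_id`, `subject_id`, `activity_code`,
  `sampling_rate`.
* `signals/<trial_id>.csv` — `time_s, ax_g, ay_g, az_g` in units of g.

Units are normalised to g at ingest because the feature definitions and
the generator's kernel contracts are stated in g. The time column is
redundant when a sampling rate is declared; if both are present and
disagree by more than 1% validation fails (sampling jitter beyond that is
not modelled). All references are checked at construction, and every
split plan is audited against the dataset before an experiment runs.

## The synthetic generator

The generator emulates the *statistical structure the features are meant
to detect*, not biomechanics. Each trial is a deterministic
magnitude-and-tilt template per activity category plus independent
per-axis Gaussian noise:

* **fall** — rest at 1 g, a free-fall valley dipping the signal magnitude
  to ≈ 0.25 g, an impact peak ≈ `1 + 2.2·gain` g ~0.3 s later, then a
  rotation of the gravity direction to the horizontal (the subject ends
  lying down).
* **basic** — gentle oscillation, magnitude confined to [0.7, 1.5] g;
  `standing` has zero oscillation (pure gravity).
* **standard** — stronger oscillation, no impact.
* **sporting** — sharp periodic peaks above 2 g *without* a preceding
  sub-0.6 g valley, with moderate dips to ≈ 0.75 g.
* **near_fall** — a valley to ≈ 0.65 g and a recovery peak well below a
  fall impact, returning to upright rest.

`gain = 1 + 0.5·coupling·(h·w / h₀·w₀ − 1)` couples a subject's
height-weight product (normalised by the configured range midpoints,
h₀·w₀) to event amplitudes. The factor 0.5 compresses the cohort's spread
so that even the lightest subject's fall impact clears 2 g and sporting
peaks stay above 2 g — the category contracts hold for every subject. The
free-fall valley is deliberately *not* coupled: free fall is
mass-independent. With `amplitude_coupling = 0` the build has no effect
on the signal, which provides the null condition for the
characteristic-split experiments. An optional `age_effect` switch widens
event transitions by up to ~25% across the adult age span, mimicking
slower reactions; it is off by default.

Default study conditions, chosen once: 10 subjects, 2 trials per subject
per category (100 trials, 20 falls), 50 Hz, 10 s trials, coupling 1,
noise sd 0.03 g, subject ranges 18–75 years / 149–193 cm / 41.5–102 kg —
the span of the public waist-worn repositories. These sizes keep a full
grid-times-five-folds experiment under a few seconds on one CPU while
leaving every group large enough for the fair round-robin distribution.

What the generator does **not** emulate: realistic fall biomechanics,
sensor orientation drift, inter-trial variability of real humans, class
imbalance of real repositories, or any particular dataset's empirical
distributions. Passing tests therefore show that the *pipeline* behaves
as specified and that the directional findings hold under the generator's
assumptions — not that a particular real-world accuracy will be attained.

## Windowing and the twelve features

Falls concentrate their evidence around the impact, so each trial is
reduced to a 2-s observation window: `round(rate)` samples either side of
the sample with the highest signal magnitude vector,
`SMV_i = sqrt(ax_i² + ay_i² + az_i²)`. Ties break to the earliest index.
A peak near an edge *shifts* the window inward rather than truncating or
zero-padding it (padding would distort the jerk and spectral features);
trials shorter than 2 s are used whole.

The twelve features, with the conventions this package fixes where the
field leaves them open:

| # | feature | definition |
|---|---------|------------|
| 1 | `mean_smv` | mean of SMV |
| 2 | `std_smv` | sd of SMV |
| 3 | `mad_smv` | mean |ΔSMV| between consecutive samples |
| 4 | `rot_angle` | mean of `acos(⟨a_i, a_{i−1}⟩ / (|a_i||a_{i−1}|))`; zero-norm pairs skipped |
| 5 | `horiz_mag` | mean magnitude of the two axes orthogonal to the vertical; the vertical axis is auto-detected per window as the axis with largest mean |value|, overridable per dataset (sensor mounting differs across repositories) |
| 6 | `max_pair_diff` | `max_{i,j} |a_i − a_j|` — the *vector* reading; it may exceed `max_smv − min_smv` |
| 7 | `max_smv` | maximum SMV (impact) |
| 8 | `min_smv` | minimum SMV (free-fall valley) |
| 9 | `skew_smv` | Fisher–Pearson skewness of SMV; 0 at zero variance |
| 10 | `sma` | signal magnitude area, `(1/N) Σ (|ax|+|ay|+|az|)` |
| 11 | `dft_energy` | per axis `(1/N) Σ_k |X_k|²` with the per-axis mean removed first, summed over axes |
| 12 | `mean_autocorr` | mean of the biased sample ACF of SMV over lags 1…⌊N/2⌋; 0 at zero variance |

The DC term is excluded from the spectral energy so the 1-g gravity
component does not dominate; by Parseval the feature then equals the
time-domain sum of squared deviations, which is how the tests verify the
FFT route independently. A consequence worth noting: with per-axis means
removed, the summed energy is the squared Frobenius norm of the centred
sample matrix and is therefore invariant under rigid rotations of the
sensor frame, as are features 1–4, 6–9 and 12; only the horizontal
magnitude (5) and the SMA (10) are axis-dependent. The property tests
assert exactly this partition.

Features are z-scored with the population (divide-by-N) convention.
By default the statistics are fitted on each fold's training rows only
and applied to its test rows (leakage-free); `standardize = "global"`
reproduces the older protocol of normalising the whole table before
splitting. Both modes are recorded in the experiment object.

Degenerate inputs are values, not errors: a constant-SMV window has
skewness and mean autocorrelation 0, and zero-variance feature columns
standardise to 0 with a warning.

## Partition protocols

* `fair_fivefold` — the baseline: trials of each (subject, activity)
  group are dealt round-robin in seeded random order across five folds,
  so every subject and every activity type reaches every training side
  where counts permit; groups smaller than five simply reach fewer test
  folds.
* `subjectwise_random_fivefold` — subjects, not trials, are partitioned;
  no subject contributes to both sides of a fold. This is the control
  that separates "the test subjects are new people" from "the test
  subjects are physically different people".
* `characteristic_split` — subjects sorted by weight, height, BMI or age
  (ties by subject id); the M subjects at one extreme train, the rest
  test, with M the integer closest to 80% of the cohort (round half up:
  38 → 30, 17 → 14). Both directions are provided. A fixed
  attribute-threshold variant can be expressed through
  `age_threshold_split`'s pattern but is not part of the default
  experiment set.
* `gender_split` — train on one sex, test on the other; the 80/20 rule is
  deliberately abandoned.
* `age_threshold_split` — boundary age goes to the "older" side. A test
  side without falls is legitimate and yields the `n.c.` sentinel
  downstream.
* `category_holdout` — all ADL trials of the held-out sub-categories are
  used exclusively for testing, so test specificity is measured on the
  held-out movements alone. Fall trials are dealt across the folds with
  the fair round-robin machinery so both sides retain falls from all
  subjects and sensitivity stays computable; this reconstruction is
  recorded in the plan metadata.

Every plan is deterministic given (dataset, parameters, seed), audited
for disjointness, coverage and subject-exclusivity, and serialisable to a
`(fold, role, trial_id)` CSV with a metadata sidecar for exact re-runs.

## The classifier grid

`model_grid()` enumerates four families in a canonical, documented order
(SVM kernels; KNN distance-major, K-minor; NB; DT) — 4 + 12 + 2 + 2 = 20
variants:

* **SVM**: linear, quadratic, cubic and medium-Gaussian kernels, box
  constraint 1. "Medium Gaussian" follows the common toolbox preset of
  kernel scale √d (d = number of features), i.e. an RBF kernel with
  `gamma = 1/d`. Backed by `e1071::svm` (libsvm).
* **KNN**: Euclidean, Minkowski (exponent 3 — the "cubic" preset;
  exponent 2 would duplicate Euclidean), Chebychev and cosine distances,
  K ∈ {5, 10, 50}, uniform weighting, majority vote with ties resolved by
  the single nearest neighbour. K larger than the available neighbours is
  clamped to n−1 with a warning. Implemented directly: no installed
  package offers these metrics.
* **Naive Bayes**: Gaussian densities (`e1071::naiveBayes`) or
  per-feature, per-class kernel density estimates with normal-reference
  (Silverman) bandwidths, implemented in the package.
* **Decision tree**: `rpart` with Gini impurity, grown unrestricted and
  pruned back to at most 4 ("coarse") or 100 ("fine") internal splits.

Class imbalance is left untouched — sensitivity and specificity are
reported precisely because test sets are unbalanced. All variants are
deterministic given (spec, data, seed).

## Metrics and aggregation

With falls as positives: sensitivity `Se = 100·TP/(TP+FN)`, specificity
`Sp = 100·TN/(TN+FP)`, combined as the geometric mean √(Se·Sp), all on
the 0–100 percent scale, rounded only at rendering (2 dp). A metric whose
denominator class is absent is *not computable*: it is carried as an
explicit `NA` sentinel, rendered `"n.c."`, and propagates through the
geometric mean and fold aggregation rather than raising an error.

Fold aggregation reports both conventions, because they differ by a
Jensen gap and published tables are not always explicit about which was
used: the arithmetic mean of per-fold geometric means
(`gmean_perfold`, with its sample sd) and the pooled
√(mean Se · mean Sp) (`gmean_pooled`). Experiment rankings and the
"best model" tie-break (canonical grid order) use the pooled value.

## What the directional experiments show

On the default synthetic conditions the fair fivefold baseline is
essentially perfect for the stronger variants — by construction, since
the kernels separate cleanly in the twelve features. The interesting
comparisons, each computed by the test suite and the acceptance script:

* holding out sporting ADLs from training collapses test specificity
  relative to the fair split: high-energy peaks unseen in training are
  read as impacts;
* with amplitude coupling on, characteristic-sorted subject splits never
  beat the fair baseline by more than fold noise; with coupling off, the
  highest-vs-lowest weight gap shrinks toward zero.

## Known limitations

* The generator's linear build-to-amplitude coupling is a stand-in for a
  qualitative claim; its gain is a free parameter, not an empirical
  value.
* Only accelerometry is modelled — no gyroscope, magnetometer, barometer
  or heart-rate channels.
* No resampling across sampling rates: features are computed at native
  rate, which is safe because train and test always come from the same
  dataset in every supported protocol.
* Hyperparameters are fixed a priori; there is no nested tuning, and the
  alternative massive-feature-extraction route is supported only through
  the external feature-table hook of `run_experiment()`.
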