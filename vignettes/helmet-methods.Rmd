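---
title: "HELMET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HELMET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the data
model and target construction, the transition-weighted training loss,
the comparator and evaluation suite, the synthetic-cohort generator, and
the numerical and design choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## Clinical setting and data model

After a large middle cerebral artery stroke, malignant cerebral edema
pushes the brain across the midline. The millimetre displacement of the
septum pellucidum — the midline shift, MLS — is the standard
radiographic severity marker, and the quantity this package predicts.
All time is indexed in hours from the moment the patient was *last seen
well* (LSW); admission is required to occur within 24 h of LSW, matching
the usual inclusion criterion for this population.

A hospitalization (`patient_record()`) consists of a static profile, a
long table of timed dynamic measurements, a time-sorted scan table of
human-extracted radiographic variables, timed treatments, and a
discharge/censoring hour. MLS maps onto four ordinal classes:

| code | label  | interval (mm) |
|------|--------|---------------|
| 0    | 0mm    | {0}           |
| 1    | 0-3mm  | (0, 3]        |
| 2    | 3-8mm  | (3, 8]        |
| 3    | >8mm   | (8, ∞)        |

**Boundary convention.** The clinical thresholds at 3 mm and 8 mm leave
boundary membership ambiguous. We assign exact boundary values to the
lower class: this keeps the top class strictly "exceeding 8 mm" and
makes the mapping a right-continuous step function. The same convention
(boundary down) is used by the 5 mm binary sensitivity mode.

## Hourly observations

`build_hourly_grid()` produces consecutive integer hours from the first
whole hour at or after admission until discharge, censored strictly
before a decompressive hemicraniectomy (post-surgical anatomy no longer
reflects the modelled process) and truncated 168 h (7 days) after
admission — edema virtually always peaks and recedes within this span.
The truncation cap is expressed as `admission_hour + 168` on the LSW
axis, since admission is the natural origin for "first seven days of
hospitalization" while all indices live on the LSW axis.

Each dynamic and radiographic variable contributes two derived features
per hour *h*:

* forward-fill `*_ff`: the most recent raw value with event hour ≤ *h*
  (sub-hour ties: the latest value wins);
* rolling maximum `*_max24`: the maximum raw value with event hour in
  the half-open window (*h* − 24, *h*] (sub-hour aggregation: the max).

Forward-fill is idempotent, and the rolling maximum dominates the
forward-filled value whenever the latter's event lies inside the
window; both properties are asserted in the tests. A 73rd radiographic
feature, `mls_prior_ff`, forward-fills the last known MLS *prior to the
most recent measurement*, characterizing the trajectory's direction.
With the reference schema (33 static / 16 dynamic / 36 radiographic
variables plus 12 text-probability columns) every observation has
33 + 32 + 73 + 12 = 150 features, each tagged with one of four
categories (`static`, `dynamic_ehr`, `human_radiographic`, `llm_text`).

**Imputation.** Static features are mean-imputed with means fitted on
the training-split patients only; fitting on the full cohort would leak
test-set statistics, so the split loop refits the imputer per split.
Derived dynamic/radiographic columns that are still missing (no
measurement yet) are left `NA` in the observation table and mean-imputed
at model-fit time with training-split *column* means stored inside the
model bundle — an extension of the static mean-imputation mechanism to
derived columns, applied identically at prediction time so the design
matrix stays rectangular. The prior-MLS feature before a second scan
exists is handled by the same rule.

## Targets and the filtered set

For horizon *W* ∈ {8, 24} (36 exists only to train the text-feature
models, mirroring the role of longer-horizon labels in report
classification), the target at hour *h* is the class of the maximum MLS
over scans in the half-open window (*h*, *h* + *W*]. The window is open
on the left so a scan at the observation hour cannot satisfy its own
window; with this convention, two scans 40 h apart on the 24-h task
leave exactly hours 0–15 after the first scan invalid and hours 16–39
valid (24 observations, all targeting the second scan), and each scan
can be targeted by at most *W* observations. Observations whose target
class differs from the current class carry the `filtered` flag; this
transition subset is both up-weighted in training and reported
separately in evaluation.

## The transition-weighted loss

Training minimizes

$$L(\mathbf{y},\mathbf{p}) \;=\; -\sum_{i\in\mathcal{F}}\sum_{c=1}^{C} y_{i,c}\log p_{i,c}
\;-\; w \sum_{i\in\mathcal{NF}}\sum_{c=1}^{C} y_{i,c}\log p_{i,c},$$

with $\mathcal{F}$ the filtered observations and $w$ the non-filtered
weight. $L$ is affine in $w$ with slope equal to the non-filtered
subset's cross-entropy — a property the tests exploit by evaluating at
three collinear $w$ values. The loss is fed to XGBoost as a custom
objective on softmax margins with gradient $u_i\,(p_{i,c}-y_{i,c})$ and
diagonal curvature $2\,u_i\,p_{i,c}(1-p_{i,c})$, where $u_i = 1$ for
filtered and $w$ otherwise. The factor 2 matches the scaling of the
library's builtin softmax objective, so $w=1$ training coincides
*exactly* (verified to float precision in the tests) with standard
multiclass log-loss training — a useful reduction case. Probabilities
are clipped at $10^{-12}$ inside logarithms.

We accept $w$ in $(0, 1]$ rather than the open interval: $w=1$ is the
unweighted limit needed for the reduction test and is a legitimate
configuration.

**Hyperparameters.** The default is $w = 0.5$, 150 rounds, depth 4,
learning rate 0.1, 80% row/column subsampling — ordinary magnitudes
for tabular boosting at this scale; they are package defaults, not
values carried over from any particular fitted model.
`tune_w_and_params()` replaces external Bayesian-optimization tooling
with a seeded random search over the same space, scored — like the
original objective — by *filtered* AUROC on an inner patient-level
80/20 validation split, falling back to overall AUROC with a warning if
the inner split holds no transitions. Training is single-threaded with
a fixed seed, so models, metrics and artifacts are bit-reproducible.

**Splits.** Resampling is implemented as five independent random 80/20
patient-level partitions (a bootstrap-resampling variant could be added,
but independent splits are the plainer scheme and are what
`make_splits()` implements). Patient-level splitting is
what rules out within-patient leakage; the acceptance tests verify
disjointness for every split.

## The EDEMA-style comparator

The baseline is a 4-class multinomial logistic regression on the eight
inputs of the published EDEMA score: admission glucose, admission
HbA1c, prior stroke, thrombectomy at any point, thrombolysis (tPA) at
any point, most recent glucose, basal cistern effacement on the most
recent scan, and the most recent MLS. The "at any point" treatment
flags are deliberately static — they are 1 even at hours before the
treatment, reproducing the original score's admission-style encoding.
The model is retrained per cohort and task on the same splits as HELMET
(the published score's coefficients are not reused), with a small ridge
penalty ($\lambda = 10^{-3}$) for numerical stability.

## Evaluation

AUROC and AUPRC are binary notions, so the 4-class task is scored
one-versus-rest: at each threshold $t$, per-class TPR, FPR, precision
and recall are computed from $p_{\cdot,c} \ge t$ and averaged across
classes with weights equal to the class's observation count; sweeping
$t$ traces the weighted ROC and PR curves, and areas come from
trapezoidal integration. The threshold grid is 1001 equally spaced
points in $[0,1]$ *plus every observed score*, which pins the swept
step function exactly and makes the areas grid-insensitive — the tests
require agreement within $10^{-6}$ with an independent brute-force
unique-cutoff implementation. A class with no predicted positives at a
threshold takes precision 1 (the empty-prediction limit). Under this
construction, uniform-random predictions on a balanced 4-class set
score AUROC ≈ 0.5, AUPRC ≈ 0.25, accuracy ≈ 0.25 — the random-guess
baselines reproduced by the acceptance suite at n = 50,000.

Accuracy is the argmax hit rate, ties broken to the lowest class code.
Sensitivity and specificity use the worsening reformulation: truth is 1
iff the target class exceeds the current class, prediction is 1 iff the
argmax class exceeds the current class; a persistence predictor
therefore has sensitivity 0 and specificity 1, and a patient already in
the top class can only contribute true negatives. Metrics undefined on
a subset (empty filtered set, single-class targets, one-sided worsening
labels) are reported as `NA`, never zeroed or dropped silently.

Split-level results are summarized as mean ± $t_{0.975,\,k-1}\,s/\sqrt{k}$
over the $k$ splits; the t-interval is our construction of choice for
five-way split summaries, and identical split values collapse to a
zero-width interval.

## Text features

Radiology reports are cropped to their Findings and Impression sections
(case-insensitive header match, any order; a report with neither header
passes through whole, with a warning). The production-scale approach —
a fine-tuned clinical transformer per horizon — is out of scope here;
the package defines the *interface* (twelve per-scan class
probabilities, 4 classes × 3 horizons, each 4-vector on the simplex
within $10^{-9}$) and ships a desk-scale stand-in: ridge multinomial
regression on token counts, deterministic given the seed, with a
patient-level 80/20 text split for held-out accuracy. An external
transformer adapter honouring the same interface can be swapped in
unchanged (a typical fine-tuning configuration is six epochs at an
initial learning rate of 2×10⁻⁵). In fully synthetic runs the
probabilities come directly from the simulator; since precomputed and
classifier-produced probabilities pass through the same validated
interface, downstream results are identical for equal values.

## Feature importance

`shapley_values()` uses tree-path-dependent exact SHAP attributions of
the boosted ensemble, per observation, feature and class, on the margin
scale; local accuracy (base value + contributions = margin) is asserted
to $10^{-6}$. The aggregation statistic — mean absolute attribution
over observations, summed over the four classes — is our choice of a
simple, sign-free aggregate; rankings and top-20 category compositions
(optionally stratified by the observation's current MLS class) are the
reported outputs. Absolute Shapley magnitudes are not interpreted,
only relative composition.

## The synthetic cohort generator

Real cohorts for this problem are protected health records, so the
package includes a generator whose *defaults are the study conditions*
the pipeline assumes:

* admission uniform within 24 h of LSW; length of stay log-normal
  (median ≈ 220 h, i.e. ≈ 9 days) so most grids reach the 7-day cap;
* scans at gamma-distributed intervals, mean 11.3 h
  (derivation profile) or 18.8 h (validation profile), shape 1.6 so
  the spread is comparable to the mean;
* MLS trajectories from a piecewise log-exponential rise/decay family:
  near zero at LSW, peaking in a configurable window (default 48–120 h,
  the classical 2–5-day edema peak), then receding with a 96-h
  half-life, plus Gaussian measurement noise (SD 0.25 mm) frozen per
  seed at integer hours and interpolated. The family is deliberately
  simple — the literature gives peak-timing folklore, not a generative
  model — and is config-swappable;
* the eventual maximum class drawn from a configurable mix (default
  0.10/0.25/0.40/0.25, consistent with a cohort whose mean maximum MLS
  is around 6–7 mm);
* WBC, temperature and sodium receive an additive ramp starting 12 h
  before each class up-transition, scaled by `signal_strength` — the
  dynamic biomarkers reported to drift before deterioration; all other
  dynamic variables are AR(1) noise around per-patient baselines;
* treatments correlate with severity; hemicraniectomy (probability 0.3
  given a severe-class trajectory) censors all later data;
* report probabilities are Dirichlet draws whose concentration is
  raised on the true future window-max class of the noiseless curve by
  `text_informativeness` (0 = uninformative, expectation uniform);
* missingness is missing-completely-at-random per variable family
  (defaults 0.10 static, 0.25 dynamic, 0.10 radiographic).

All randomness flows from one master seed through per-patient
sub-seeds, so cohorts are byte-reproducible and sub-streams do not
disturb the caller's RNG state.

**What the simulator does not emulate** — and hence what passing tests
do *not* show about real data: informative missingness, EHR-system
regime changes, inter-site population differences beyond scan cadence,
measurement error in human labels, report-text style, and any real
demographic joint distribution. The simulator demonstrates that the
pipeline recovers planted signal under the assumed structure; it cannot
certify clinical performance.

The exact membership of the 33/16/36 variable lists in the reference
schema is our instantiation of plausible clinical content at the stated
cardinalities; users with real data supply their own name lists via
`feature_schema()`.

## Problem sizes and determinism in the test suite

The suite exercises: unit oracles at toy sizes; the random-guess
baselines at n = 50,000; the curve-area oracle at n = 200 over repeated
draws; and a full signal-recovery comparison (HELMET vs the EDEMA-style
baseline, five splits, filtered AUROC) on a 300-patient simulated
cohort with 80 boosting rounds — sizes chosen so the whole suite runs
in a few minutes on one core while still giving the comparison a clear
margin. All stochastic tests fix their seeds; XGBoost runs
single-threaded histogram construction, so every reported number is
bit-reproducible.

## Known limitations

* The 5 mm binary mode takes its truth from the continuous window
  maximum; class bins alone cannot resolve 5 mm inside the 3–8 mm
  class, so callers provide the positive-class probability (the
  pipeline uses the mass on classes above 3 mm as a serviceable
  default).
* The flat 4-class formulation ignores class ordering at training
  time (no ordinal-regression variant), matching the framework it
  implements.
* Mean imputation is deliberately simple; no model-based imputation is
  attempted.
* The stand-in text classifier is a bag-of-words model: adequate to
  exercise the interface and the synthetic corpus, not a substitute for
  a clinical transformer on real reports.
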