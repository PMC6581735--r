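---
title: "Connectome-based biomarkers for subclinical depression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sdconnect` turns per-subject ROI time series into weighted functional
brain networks, screens their edges for group differences between
subclinically depressed (SD) and healthy-control (HC) subjects, trains
SVM classifiers on the selected connections under leave-one-out
cross-validation (LOOCV), and profiles the regions, subregions and
connections that carry the signal. This vignette is the package's own
account of those methods: the model and its assumptions, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the design choices made where the design was genuinely open.

## From time series to networks

Each subject contributes a T × N matrix (T timepoints, N atlas
subregions). Edge weights are

W_ij = |arctanh(r_ij)| / max |arctanh(r)| over the off-diagonal,

with `r` the Pearson correlation matrix. The arctanh (Fisher r-to-z)
transform is variance-stabilising and strictly monotone in |r|, so the
within-subject ranking of edges by correlation magnitude is preserved —
a property the test suite asserts. Taking absolute values reflects the
unresolved interpretation of negative resting-state correlations: the
pipeline treats anticorrelation strength like correlation strength and
offers no signed-network mode.

Three numerical choices here were open and are worth recording:

* **Normalisation.** "Normalised absolute value" does not pin down the
  denominator. The default divides each subject's |z| matrix by its own
  off-diagonal maximum, so every subject's strongest edge has weight 1
  and all weights lie in [0, 1]. A cohort-wide alternative
  (`build_networks(..., normalization = "cohort")`) divides all subjects
  by the single largest |z|, preserving between-subject weight scale at
  the cost of no longer giving each subject a unit maximum. Per-subject
  is the default because it is the simplest map satisfying the [0, 1]
  constraint and leaves within-subject edge ranking untouched; both are
  tested.
* **Perfect correlations.** |r| = 1 off the diagonal has infinite z; it
  is clipped at `arctanh(1 - 1e-7)` with a warning. Real data never get
  there, but synthetic edge cases and duplicated columns do.
* **Diagonal and degenerate input.** Self-connections are fixed at 0 and
  excluded from normalisation and from degree sums. A constant column
  (zero variance) is an error naming the subregion, raised at network
  construction and flagged earlier by the file reader.

Weighted node degree is `k_i = sum_j W_ij`, the row sum over the
symmetric weight matrix.

## Edge screening and the leakage-avoiding mask family

Each of the N(N−1)/2 edges is compared between groups with a two-sample
t-test on its per-subject weights (pooled variance by default; Welch by
`var_equal = FALSE`). Benjamini–Hochberg adjusted q-values are computed
for every table. An edge enters the significance *mask* when its
uncorrected p-value is below `alpha` (default 0.05).

Two decisions deserve comment:

* **p, not q, gates the mask by default.** The screening here is a
  feature-selection step feeding a classifier, not a final inference;
  gating on uncorrected p keeps enough candidate connections for the
  models while the q-values remain available for group-level reporting.
  `build_mask_family(..., criterion = "q")` switches the gate to the
  BH-adjusted values for users who want strict control.
* **One mask per LOOCV fold.** If edges were selected using all subjects,
  the held-out subject would have influenced its own feature set — a
  classic information leak that inflates cross-validated accuracy. The
  mask family therefore holds the full-cohort mask (used only for
  group-level profiling) plus one mask per subject computed with that
  subject excluded; `loocv_evaluate()` consumes only the fold masks. The
  test suite verifies, by recomputation, that corrupting a held-out
  subject's network changes neither its fold mask nor the tuned
  hyper-parameters of its fold.

## Feature families and their scope

Three families of connection sets define the classifiers:

* **Anatomical**: one model per merged (bilateral) region, using the
  masked connections *incident* to its subregions. With the default
  atlas layout — 24 bilateral regions over 246 subregions, thalamus
  holding 16 — this gives the 24 region-based models.
* **Sliding windows**: N − w + 1 windows of w consecutive subregions in
  atlas order (231 windows of 16 for N = 246), using the masked
  connections *within* each window.
* **Random selections**: uniform draws of w subregions without
  replacement, again using the connections *within* the set.

The scope split (incident for anatomical, within for window/random) is a
deliberate design choice. With incident scope a node set inherits every
masked edge that touches it from anywhere in the graph; since a strong
effect concentrated on one region touches all other nodes through its
incident edges, *any* random set would inherit the informative edges and
random models could never fall behind region models — erasing the
contrast the three families exist to exhibit (coherent anatomical units
versus arbitrary subregion collections). Within scope confines window and
random models to their own node set's internal connections, which is also
the natural reading of those families as self-contained subregion sets.
Both scopes remain available per family, and `pipeline_config(scope =)`
can force either everywhere.

## Classifier, tuning, and evaluation

Models are RBF-kernel SVMs (via libsvm, through `e1071`):
`K(x, x') = exp(-gamma ||x - x'||²)`, grid-searched over
`C = 2^-5, 2^-3, …, 2^15` and `gamma = 2^-15, …, 2^3` — the standard
libsvm grid. Inside every LOOCV fold, the grid search runs a stratified
inner cross-validation (5-fold by default) on the training subjects only;
the winning pair is refit on all training subjects and predicts the
held-out subject. Ties in inner-CV accuracy break toward the smallest C,
then the smallest gamma — preferring the smoothest model and making the
whole procedure deterministic given the configuration seed. A `"global"`
grid mode (tune once on the full cohort) exists for comparison but is not
the default, since nested tuning is the defensible choice when the tuning
set must not see the held-out subject.

Features are the raw edge weights, already bounded in [0, 1] by
construction, so no additional scaling is applied by default
(`scale_features = TRUE` adds per-fold standardisation). A fold whose
mask yields no features predicts the training majority class with
decision value 0 and is flagged in the per-fold table rather than
crashing the run.

Evaluation pools the per-fold decision values into a single ROC curve;
the AUC is the rank-based Mann–Whitney statistic with half-credit ties,
which equals the trapezoidal area under the swept curve (asserted against
a pairwise-enumeration oracle and against `pROC` in the tests). The
confusion matrix takes SD as the positive class, so sensitivity is the
detection rate among SD subjects and specificity the correct-rejection
rate among HC.

## Region, subregion and degree profiling

Group-level profiling uses the full-cohort mask (fold masks exist for
prediction only). Per region: the number of masked incident connections
(an intra-region edge counts once) and their mean p-value. For a focal
region, partner attribution assigns each connection to the merged region
of its other endpoint, with intra-focal edges attributed to the focal
region itself, so partner counts sum exactly to the focal count.
Hemispheric profiles split each merged count by the hemisphere of the
endpoint inside the region (both-endpoint edges go to the lower-indexed
endpoint's hemisphere), so left + right always reproduces the merged
count. Subregion profiles count edges incident to each focal subregion,
an intra-focal edge counting for both of its endpoints.

The confounder check correlates per-region model accuracy with connection
count and with mean p (Pearson, two-sided), and
`subsample_connections_experiment()` re-runs a model's LOOCV with a
random subset of its masked connections — the test of whether a
high-performing region survives having its connection count reduced to
another region's.

Node degree is compared per subregion with a pooled two-sample t-test at
alpha = 0.01 by default, reporting the direction (SD below or above HC)
for significant subregions; the parcellation's LHb flag marks the
subregion containing the lateral habenula so its laterality can be read
directly off the table.

## The synthetic cohort generator

Because no clinical data ship with the package, the generator is a
first-class module. Per subject it draws T i.i.d. samples from a
multivariate normal whose correlation matrix is a shared block structure
(within-region correlation 0.3, between-region 0.1) with three layers on
top:

1. **Planted effects.** Edges incident to the designated regions shift by
   ±effect/2 per group — SD down, HC up — so the group difference in
   population correlation equals `effect_size`. The SD-down default
   matches the decreased-connectivity direction the degree comparisons
   are designed to detect.
2. **Between-subject heterogeneity.** Every edge correlation receives a
   per-subject Gaussian perturbation (SD 0.15 by default) before
   sampling. Without it, within-group edge variance would come only from
   finite-T sampling noise and a two-sample test would be miscalibrated
   relative to real cohorts. The value 0.15 reflects the between-subject
   spread of edge-wise resting-state correlations commonly seen in
   test-retest and cohort data (SD of r around 0.1–0.2); much smaller
   values make every cohort perfectly separable, a regime in which all
   model families saturate and become indistinguishable.
3. **PSD repair.** After shifts and perturbation the matrix may lose
   positive semidefiniteness; negative eigenvalues are clipped to a 1e-8
   floor and the diagonal renormalised to 1. If repairing the *group*
   matrix moves any planted edge by more than 0.05 from its target, the
   shift is declared infeasible and the offending edge named.

Demographics are sampled group-matched in expectation (age 19–25,
education ≈ 13 years, BDI-II > 13 in SD only), and
`compare_demographics()` applies the same tests a participant table would
get: pooled t for age and education, chi-square (uncorrected) for sex.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: temporal autocorrelation of the
BOLD signal (samples are i.i.d. in time; the pipeline only consumes
sample correlations, but effective degrees of freedom on real scans are
lower than T), motion and physiological artefacts, site and scanner
effects, non-Gaussian tails, and effects that are diffuse rather than
concentrated on named regions. Calibration results (5% null edge rate,
chance-level null classification) transfer to real data only insofar as
those ignored features behave benignly.

## Problem sizes and the acceptance script

The test suite and `scripts/acceptance.R` run the study design at two
scales, chosen as the package's own validation sizes: the full design
(74 subjects, 246 subregions, 180 timepoints) wherever only masks and
counting are involved, and a 60-node scale for the model-fitting
experiments (40 + 40 subjects, effect 0.4, 180 timepoints), with a
reduced SVM grid (C ∈ {2¹, 2⁷}, gamma ∈ {2⁻⁷, 2⁻³}, 3 inner folds) so
that repeated LOOCV over many seeds stays tractable. At that scale the
focal region keeps the full atlas's thalamus proportion (6 of 60 ≈ 16 of
246) and the random sets match the focal region's size, exactly as the
study matched its random selections to the thalamus. Under those
conditions the planted region's model separates the groups essentially
perfectly, random-selection models average noticeably lower (many contain
no planted node and sit near or below chance), null cohorts stay at the
nominal 5% edge rate and near-chance LOOCV accuracy, and the LHb-flagged
subregion is reliably called SD-below-HC.

One published number the package deliberately does not reproduce: a
percentage cell in the study's confusion tables ("37 (94.4%)" for the
cingulate model) that is inconsistent with the column-normalised
convention used by every other cell; `confusion_metrics()` reports
standard column-normalised values throughout.

## Known limitations

* LOOCV accuracy on null data is biased slightly below 0.5 (the training
  set always under-represents the held-out class by one); the chance-level
  checks use a band around 0.5 rather than a point value for this reason.
* The subsampling experiment thins fold masks by intersection, so a
  repeat can run with fewer than `target_n` features in some folds; this
  is logged, not hidden.
* With very small groups the stratified inner CV can produce single-class
  training splits; those splits fall back to majority-class prediction
  inside the grid search rather than failing the whole fold.
* The pipeline assumes one fixed parcellation across subjects and does
  not model parcellation uncertainty or voxel-level localisation; the
  LHb is represented by a subregion flag, not coordinates.
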