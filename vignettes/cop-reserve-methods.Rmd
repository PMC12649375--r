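---
title: "Temporal COP analysis for compensatory reserve: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal COP analysis for compensatory reserve: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copreserve)
```

# The problem

Sarcopenia — age-related loss of muscle mass, strength and performance —
degrades postural control, but affected individuals often compensate well
enough that scalar posturographic summaries (sway amplitude, mean velocity)
stay within normal limits in easy stances. `copreserve` analyses the
*temporal structure* of center-of-pressure (COP) trajectories instead. Two
outputs matter: whether the temporal features separate patients from
controls at all (a binary classification task that validates the features),
and, within diagnosed patients, how widely the model's out-of-fold
predicted probability P(Y = 1) spreads. That spread is read as a gradient
of **compensatory reserve**: a patient whose COP dynamics sit close to the
healthy norm (low P(Y = 1)) is compensating effectively; one far from it
has depleted reserve.

The analysis unit is the subject × posture. Six channels are recorded per
trial — left foot, right foot and overall centre, each in the mediolateral
(X) and anteroposterior (Y) direction — at 100 Hz for 20 s, typically three
trials per posture, in feet-together (FT), feet-apart (FA) and semi-tandem
(ST) stances. Postures are processed independently end to end: normative
sway differs by stance, so templates, features, models and reports are all
posture-specific, and no cross-posture pooling occurs.

# Preprocessing

Per channel, in fixed order:

1. **Outlier replacement.** The mean µ and population SD are computed once
   over the full series; points with |x − µ| > 3·SD are replaced by µ. The
   moments are *not* recomputed after replacement (one flag-then-replace
   pass), and a constant series is returned untouched. The rule targets
   isolated transduction artefacts; a warning is emitted if five or more
   contiguous samples are replaced in one run, since that pattern suggests
   a real excursion rather than an artefact. Replacement can never increase
   the series SD (tested as a property).
2. **Origin translation.** The first sample of each channel is subtracted
   from the whole channel, removing initial placement differences while
   preserving all relative displacements. Subtracting the first sample
   (rather than the mean) is deliberate: the purpose is alignment of the
   *starting* position, and the operation is idempotent.
3. **Z-score.** Centre and scale by the population SD; a constant channel
   maps to zeros.

Both the translated (mm) and standardized (unitless) variants are kept.
Template construction, DTW and the LSTM embeddings consume the standardized
variant, so that deviation features compare *shape*, not amplitude units.
The statistical descriptors default to the translated variant: the
coefficient of variation σ/µ is degenerate on Z-scored data (µ = 0 by
construction). A configuration switch (`stats_on = "standardized"`)
restores the literal Z-scored reading for sensitivity analysis, with the
CV guarded as σ/(|µ| + 1e−8) and a warning when |µ| < 1e−8.

The population-SD convention (divide by n) is used throughout this stage
for internal consistency with the Z-score guard and the reserve report; at
T = 2000 the distinction from the sample SD is negligible.

# The healthy template

Per posture and channel, the template is the pointwise **median** across
control subjects' standardized series (each subject contributing the mean
of their trials by default; `trial_aggregation = "per_trial"` lets each
trial contribute a row). The median is robust to non-normality and
transient anomalies. Before the median is taken, a two-sided Grubbs test
(α = 0.05, statistic G = max|x − mean|/s against the t-based critical
value) screens each timepoint across controls. The screen is
*diagnostic*: flags are counted and reported but values are not removed,
because post-preprocessing data should already be outlier-free and the
median absorbs what remains. `exclude_flagged = TRUE` drops the single
most extreme value at flagged timepoints for sensitivity analysis.

The template is built from **all** controls, outside any cross-validation
loop. Since only label-0 subjects enter it, it leaks no patient
information into the features; the selection and classification stages
handle label leakage separately (below). Patient data never entering the
template is asserted by a perturbation test.

# The 36 temporal features

Per subject × posture, in fixed name order:

- **6 DTW deviations** (`DTW-<channel>`). Banded dynamic time warping
  distance between the subject's standardized channel and the template
  curve, with pointwise cost |s₁[i] − s₂[j]|^γ and cumulative cost
  D(i, j) = cost + min(D(i−1, j), D(i, j−1), D(i−1, j−1)), D(0, 0) = 0.
  Template indices are constrained to a window of half-width
  w = max(1, ⌈band_fraction · max(m, n)⌉) around the sample index. The
  10% default keeps alignments physiologically plausible (≤ 2 s of warp at
  T = 2000, w = 200) and reduces cost to O(n·w). The ceiling-and-floor
  rule exists because a literal 10% window is sub-unit for short test
  series; at study scale it is exactly the 10% geometry. Infeasible band
  cells carry +∞, and an endpoint made unreachable by |n − m| > w is an
  error that names the band geometry. The exponent γ (grid
  {0.5, 1, 1.5, 2}, default 1.5) tunes sensitivity: γ > 1 emphasises
  large localized misalignments (delayed corrective responses), γ < 1
  flattens them toward benign sway; `gamma_sweep()` re-runs the pipeline
  over the grid and reports pooled F1/ROC-AUC per value.
- **12 LSTM embedding values** (`LSTM-<channel>-1/2`). The final hidden
  state of a single-layer, 2-unit LSTM run over each standardized channel:
  logistic input/forget/output gates, tanh candidate,
  c_t = f⊙c_{t−1} + i⊙g, h_t = o⊙tanh(c_t), zero initial state. The cell
  is **untrained**: weights are drawn once from uniform(−0.5, 0.5) under a
  fixed seed (default 42) with zero biases, and the same weight set serves
  all six channels. This is a reservoir-style deterministic transformer —
  it preserves sequential structure without fitting anything, which
  avoids overfitting at small cohort sizes. Zero biases make the all-zero
  input an exact fixed point (h_T = 0), which pins down the cell variant
  testably; the uniform initializer and the draw order (input weights then
  recurrent matrices, gate order i, f, g, o) are documented conventions so
  embeddings are bit-reproducible. Embeddings always lie in (−1, 1)
  because |h| = |o|·|tanh(c)| < 1.
- **18 statistical descriptors** (`cv_`, `slope_`, `iqr_` × channel).
  Coefficient of variation σ/µ (population σ), the OLS linear trend slope
  against t = 1…T (directional drift, mm/sample on the translated
  variant), and the interquartile range Q₃ − Q₁ with linear-interpolation
  quantiles (R type 7, stated so IQR values are exactly reproducible).

Trial-level vectors are averaged within subject by default (the subject is
the analysis unit; a per-trial mode is retained).

# Feature selection

Each feature i receives f(i) — the one-way ANOVA F statistic against the
label — and p(i) — mean-decrease-in-impurity importance from a seeded
500-tree random forest fit on all features jointly. The composite score is
the equal-weight normalized sum S(i) = f(i)/max(f) + p(i)/max(p) ∈ [0, 2].
Features are then traversed in descending S (ties: higher f, then
lexicographic name — a fixed rule, since ties must break identically
across runs), and a candidate is pruned when its absolute Spearman
correlation with any already-kept feature reaches 0.7. Traversal stops at
7 kept features; if fewer than 4 survive, the survivors are returned with
a warning. With N = 82 subjects and at most 7 features, N/p ≥ 11.7,
comfortably above the 10-per-feature floor for stable small-cohort fits.
The stop-at-7 reading of the 4–7 band was chosen over targeting an
interior value: more surviving de-correlated features cannot hurt a
downstream learner that re-weights them.

# Cross-validation and class imbalance

Classification uses repeated stratified 5-fold cross-validation (default 5
repeats to stabilise out-of-fold probability distributions). **Per
training fold**: feature selection is re-run on the training rows only
(default `per_fold` scope; `global` scope reproduces the
selection-before-CV order some analyses use, at the cost of optimistic
bias — both are available and logged), SMOTE balances the classes, models
are tuned by grid search maximising mean F1, fit, and applied to the
held-out fold.

SMOTE synthesises minority-class rows as x + λ·(x_nn − x), λ ~ U(0, 1),
with x_nn among the k nearest minority neighbours (Euclidean). k is
min(3, minority − 1): the −1 guard exists because a point cannot be its
own neighbour, so the cap binds correctly when the fold's minority class
has ≤ 3 members. Synthetic rows exist only inside a training fold and can
never reach a test fold; `prepare_fold()` — the function that performs all
training-side work — never receives test rows at all, which makes the
leakage guard directly testable: corrupting held-out subjects must leave
its output bit-identical.

Seven classifier families are supported (KNN, random forest, extra trees,
RBF-SVM, decision tree, Gaussian naive Bayes, logistic regression),
implemented over randomForest, ranger (`splitrule = "extratrees"`), e1071,
rpart, caret::knn3 and stats::glm. Features are standardized with
training-fold statistics for the scale-sensitive models (KNN, SVM, LR);
tree models and NB consume raw features. Hyperparameter grids are small
repository defaults (KNN k ∈ {3,5,7,9}; RF/ET trees ∈ {200,500}; SVM
C ∈ {0.1,1,10}; DT depth ∈ {3,5,30}; NB and LR fixed), not claims about
any external analysis. Two tuning modes exist because nesting is a genuine
design fork: `strict` (default) tunes by inner 3-fold CV within each
training fold; `outer` scores the grid on the outer folds, which is
simpler and common in applied work but mildly optimistic.

Metrics use the positive class Y = 1: accuracy, precision (0 with a
warning when no positive predictions), recall, F1, ROC-AUC by the rank
(Mann–Whitney) method with average-rank ties — so constant probabilities
give exactly 0.5 — and AUPR by step integration of the precision–recall
curve with tied scores grouped. A single-class truth vector leaves the
threshold-free metrics `NA` (undefined), never 0. Reports aggregate
mean ± SD across folds and repeats per classifier, and mean ± SD across
classifier means for the pooled summary.

# Interpretation and the reserve report

Attribution is pluggable; the built-in backend is permutation importance
(mean ROC-AUC drop over seeded column permutations, 10 by default) on
models refit to the SMOTE-balanced full data. Only the downstream logic is
fixed: per model, rank features by absolute attribution (ties by name),
take the top 5, and count feature-type membership (DTW / LSTM /
Statistical by name prefix) across models. Rank-based aggregation makes
the summary invariant to each backend's attribution scale.

Feature–clinical associations use Spearman's ρ with average-rank ties and
a two-sided p from the t approximation, pairwise-deleting missing clinical
values and reporting the n used; pairs with fewer than 3 complete
observations are skipped. No multiplicity correction is applied by default
(the analysis is exploratory); `adjust = TRUE` adds Benjamini–Hochberg.

The reserve report restricts to label-1 subjects (a switch includes all
subjects), averages each subject's out-of-fold P(Y = 1) over classifiers
and repeats, and summarises the subject-level distribution by range,
mean, population SD and CV% = 100·SD/mean. Interpretation cutoffs
(P > 0.7 depleted, P < 0.5 high reserve) are emitted as annotations
explicitly flagged as cohort-derived and unvalidated.

# The synthetic cohort generator

Clinical COP data cannot be bundled, so every downstream stage is
exercised on simulated cohorts whose structure matches what the features
target:

- **Controls**: each channel is a stationary AR(2) process with poles at
  radius 0.97 and a 0.5 Hz resonance — inside the 0.3–1 Hz quiet-stance
  sway band — scaled to a 2 mm stationary SD via the closed-form AR(2)
  variance, with a ±20% per-subject amplitude effect mimicking
  inter-individual variability. Any stationary low-frequency process would
  do for testing; AR(2) was chosen for the closed-form variance and cheap
  generation. 300 burn-in samples precede each trial.
- **Patients**: the same process with three pathology terms, each scaled
  by (1 − reserve): a linear drift (default 0.002 mm/sample at full
  severity — 4 mm over a 20 s trial, a realistic directional-drift
  magnitude relative to 2 mm sway), a corrective delay (default 30
  samples = 0.3 s lag of the sway process, capped at T − 1 as a
  degenerate-input guard), and a dispersion multiplier
  1 + (1 − reserve)(sway_scale − 1), default sway_scale 1.5. Drift enters
  all six channels with the same sign so a channel's fitted slope directly
  recovers the injected value. Because every term carries the (1 − reserve)
  factor, reserve = 1 is an *exact* null: a patient is generated on the
  identical random path as a control, which the null-classification tests
  rely on.
- **Clinical indicators** are monotone noisy functions of severity with
  means anchored to typical geriatric-cohort values (ASMI ≈ 6.5 kg/m²
  controls, grip ≈ 26 kg, chair-stand ≈ 8.5 s, walk speed ≈ 1.17 m/s,
  declining/increasing with severity), so correlation analyses have a
  known expected sign.

What the generator does **not** emulate: inverted-pendulum biomechanics,
intermittent postural corrections, anxiety or comorbidity confounds,
foot-specific asymmetries, and channel cross-correlation structure (the
six channels are generated independently, whereas real left/right/centre
channels are strongly coupled). Passing tests therefore demonstrate that
the pipeline recovers the *injected* effect classes — trend, delay,
dispersion, and their graded mixture — not that it would achieve any
particular performance on clinical recordings.

# Numerical and testing choices

- All stochastic stages draw from explicit integer seeds; stage seeds are
  derived from one top-level seed by a fixed mixing function, keeping
  every derived seed below 2³¹. Identical configuration and seed
  reproduce every report bit for bit.
- Drift-recovery tests compare the mean fitted slope over repeated trials
  with the injected value within 3 *Monte-Carlo* standard errors: naive
  per-fit OLS standard errors are anti-conservative under strongly
  autocorrelated sway, so the empirical SE of the mean is the honest
  yardstick.
- DTW correctness is established against an independent full
  dynamic-programming implementation on random short pairs: exact
  equality (1e−10) with the band disabled, and equality whenever the
  unconstrained optimum's backtracked path fits the default band.
- Null and strong-effect pipeline checks run the full pipeline on
  10 + 10-subject single-posture cohorts at the generator's study-scale
  trial conditions (3 × 2000-sample trials), with an RF + LR classifier
  pair and one CV repeat, averaged over 10 simulation seeds; chance-level
  behaviour on exact-null cohorts and near-perfect separation at zero
  reserve are both required. The worked-example and reproduction script
  use 30- and 82-subject cohorts respectively.

# Limitations

Simulated validation shows internal consistency, not clinical validity.
The reserve interpretation of P(Y = 1) variability inherits every caveat
of the classifier stack (calibration is not performed; probabilities are
comparable within a run, not across cohorts). The fixed-weight LSTM
embedding is a deterministic transformer whose individual coordinates have
no direct physiological meaning; only their discriminative use is claimed.
Grubbs screening assumes approximate normality across controls at each
timepoint and is applied diagnostically for that reason. Finally, the
per-fold selection default means the selected feature set can differ
between folds; the global mode gives one interpretable set at the price of
optimistic bias — users should report which mode they used.
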