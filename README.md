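# copreserve

Quantifying **compensatory reserve** in sarcopenia from force-platform
center-of-pressure (COP) recordings.

Older adults with sarcopenia can mask balance deficits through neuromuscular
compensation, so simple posturographic summaries often look normal.
`copreserve` implements a multidimensional *temporal* analysis of
quiet-standing COP signals for researchers in posturography and geriatric
movement analysis: it classifies sarcopenia versus control subjects from
six-channel COP time series and, within the patient group, quantifies the
spread of model-derived probabilities as a gradient of compensatory reserve
(low predicted probability of sarcopenia = COP dynamics close to the healthy
norm = high reserve).

## The method

Each subject stands quietly for 20 s per trial (100 Hz, 2000 samples) in up
to three postures — feet together (FT), feet apart (FA), semi-tandem (ST) —
while six displacement channels are recorded: left foot, right foot and
overall centre, each in the mediolateral (X) and anteroposterior (Y)
direction.

Per channel, the pipeline:

1. **Preprocesses**: points beyond ±3 SD of the channel mean are replaced by
   the mean, coordinates are translated so the first sample is the origin,
   and the series is Z-scored.
2. **Builds a healthy template** per posture: the pointwise median across
   control subjects' standardized series, with a diagnostic Grubbs screen
   (α = 0.05) at each timepoint.
3. **Extracts 36 temporal features** per subject × posture:
   - 6 **DTW deviations** — banded dynamic time warping distance to the
     template with pointwise cost `|s₁[i] − s₂[j]|^γ` (γ ∈ {0.5, 1, 1.5, 2},
     default 1.5) and a Sakoe–Chiba-style window of half-width
     `0.1 · max(m, n)`;
   - 12 **fixed-weight LSTM embeddings** — the final hidden state of an
     untrained 2-unit LSTM cell (seeded uniform(−0.5, 0.5) weights, zero
     biases, one weight set shared by all channels), a deterministic
     sequential transformer;
   - 18 **statistical descriptors** — coefficient of variation `σ/μ`, OLS
     linear trend slope against `t = 1…T`, and interquartile range
     `Q₃ − Q₁`.
4. **Selects features** by the composite score
   `S(i) = f(i)/max(f) + p(i)/max(p)` (ANOVA F statistic + random-forest
   impurity importance, equal weights), pruning candidates with Spearman
   `|ρ| ≥ 0.7` against any higher-ranked kept feature, down to 4–7 features
   (`N/p ≥ 10`).
5. **Classifies** with SMOTE-balanced 5-fold stratified cross-validation
   over seven families (KNN, RF, Extra Trees, SVM, Decision Tree, Naive
   Bayes, Logistic Regression), grid search maximising mean F1, reporting
   accuracy, precision, recall, F1, ROC-AUC and AUPR as mean ± SD.
6. **Interprets**: permutation attribution with top-5 feature-type
   frequencies across models, Spearman correlations of features with
   clinical indicators (ASMI, grip strength, chair-stand time, walk speed),
   and the **reserve report** — range, mean ± SD and CV% of each patient's
   out-of-fold P(Y = 1).

A synthetic cohort generator (`sim_profile()` / `simulate_cohort()`)
produces labelled test cohorts: stationary AR(2) sway for controls, and for
patients a severity-graded mixture of directional drift, delayed corrective
responses and inflated sway dispersion, each scaled by `(1 − reserve)`.

## Worked example

```r
library(copreserve)

profile <- sim_profile(n_controls = 15, n_patients = 15,
                       postures = "ST", seed = 42)
cohort  <- simulate_cohort(profile)
print(cohort)
#> COP cohort: 30 subjects (15 control, 15 sarcopenia), 90 trials
#>   trials per posture: ST=90

cfg <- pipeline_config(cv = cv_config(repeats = 2, seed = 42))
fit <- fit_reserve(cohort, cfg, seed = 42)
summary(fit)
#> Compensatory-reserve analysis: 30 subjects, postures ST
#>   ST: accuracy 0.76 +/- 0.02, ROC-AUC 0.82 +/- 0.06, 7 features
#>
#> -- ST --
#> Feature selection: 7 of 36 kept (N = 30, N/p = 4.3)
#>   selected: iqr_COP-LY, slope_COP-RY, slope_COP-LX, DTW-COP-CX,
#>             LSTM-COP-RY-2, DTW-COP-RY, LSTM-COP-CY-1
#> Compensatory reserve report (ST, patients):
#>   n = 15; Range (0.18, 0.97); Mean +/- SD 0.68 +/- 0.32; CV 46.3%
#> Top-5 attribution frequency by feature type:
#>         DTW        LSTM Statistical
#>           6           4          10
```

Because this simulated cohort draws each patient's reserve uniformly from
[0, 1], the patients span the full gradient from fully compensated (P(Y = 1)
near 0.2 — COP dynamics indistinguishable from controls) to overtly
decompensated (near 1.0); the wide CV of the out-of-fold probabilities is
exactly the intra-group variability the reserve report is designed to
surface. Classification quality (ROC-AUC 0.82 here) is driven by the
drift/delay/dispersion signatures the patients' trials carry.

A thin command-line wrapper is installed at `inst/cli/copreserve`
(`simulate`, `run` and `sweep` subcommands) for shell-based use.

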