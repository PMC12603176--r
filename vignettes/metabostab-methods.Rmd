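---
title: "Stability-validated metabolite selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-validated metabolite selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metabostab` analyses targeted metabolomics concentration panels — a
samples × metabolites matrix in µM with per-sample metadata (group, sex,
carcass weight, QC flag) and per-metabolite metadata (analyte class,
limit of detection) — to find the metabolites that reliably discriminate
a small number of sample groups. This vignette is the package's own
account of the statistics it implements: the models, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, the numerical conventions, and the design decisions that
were genuinely open.

## 1. Quality control

Each metabolite passes four checks, in a fixed order of precedence, and
the first failure is its recorded exclusion reason:

1. **CV** — the intraplate coefficient of variation over the QC
   replicate rows, `100·sd/mean`, must not exceed `cv_max` (default 20%).
   A CV that cannot be computed (fewer than two non-NA replicates, or a
   zero mean) also fails this check. With only two replicates the CV
   estimate is noisy — on synthetic panels with a true replicate CV of
   10% around 5% of metabolites still exceed 20% by chance — which is the
   realistic behaviour of a single-plate design.
2. **LOD_QC** — all QC replicate values below the metabolite's limit of
   detection (`lod_qc_rule = "all"`; `"any"` is available for stricter
   audits).
3. **LOD_SAMPLES** — strictly more than `lod_sample_frac` (default 30%)
   of the non-QC samples below the LOD.
4. **NA_ZERO** — strictly more than `na_zero_frac` of the non-QC values
   missing or zero. NA and zero are distinct states (a zero is a legal
   concentration) but count toward the same rate; the default cutoff of
   0.30 mirrors the LOD-sample rule because no separate convention is
   established for this rate.

Below-LOD values in retained metabolites are kept exactly as reported —
no LOD/2 imputation — so the analysed matrix is the measured one.

Samples are never removed by QC. The outlier screen is advisory: each
metabolite is centred/scaled, missing values are median-imputed *for
scoring only*, and a sample's score is the robust z ((d − median d)/MAD)
of its Euclidean distance d from the centroid. Scores above 3.5 are
flagged; 3.5 is the conventional robust-outlier cutoff. An all-NA sample
is always flagged. The method is a deliberate, documented choice — an
outlier step is standard in panel QC but no single procedure is
canonical, and keeping it advisory means the analysed sample set is
exactly the input sample set unless the analyst intervenes.

## 2. Covariate residualization

Per metabolite, ordinary least squares across **all** non-QC samples
pooled (group labels never enter the design):

$$y_i = \beta_0 + \beta_w w_i + \beta_s s_i + \xi_i$$

with $w_i$ the carcass weight (kg) and $s_i$ a 0/1 sex contrast (levels
sorted alphabetically, first level = 0; the mapping is stored in the
result). The residuals $\hat\xi_i$ are the data for selection, rank
statistics, forests and PCA; the descriptive concentration contrast
(Δ%, below) uses the raw concentrations.

Decisions worth knowing:

* The fit is on the concentration scale, not log concentrations
  (`log_transform = FALSE` by default): metabolite *levels* are
  modelled, and the downstream machinery (forests, rank tests) is
  insensitive to monotone rescaling of each feature. A log option
  exists. One consequence of the raw scale is heteroskedasticity — a
  group with a 3-fold higher mean also has roughly 3-fold larger
  within-group spread — which slightly blurs residual-space separation
  relative to the log scale.
* Residualization uses whatever weight–group and sex–group correlation
  is in the sample, so any chance (or real) confounding between
  covariates and groups removes some group signal along with the
  covariate effect. That is the method's point — differences explainable
  by sex or weight should not count as group differences.
* Rank-deficient designs (constant weight, single sex level) drop the
  offending term with a warning rather than failing.
* NA concentrations are excluded from that metabolite's fit and come
  back as NA residuals; metabolites carrying NA residuals are dropped
  (with a warning) from any comparison matrix that needs complete data.

## 3. All-relevant selection with shadow features

`run_boruta()` implements the shadow-feature wrapper. Per iteration:

1. append a permuted copy ("shadow") of **every** feature to the
   predictor matrix;
2. fit a random-forest classifier (`ranger`, impurity importance,
   `n_trees` per fit, single-threaded and seeded for reproducibility);
3. a still-competing real feature scores a **hit** when its importance
   exceeds the `perc` percentile (default 100, i.e. the maximum) of the
   shadow importances;
4. from iteration 5 onward, one-sided binomial tail tests on the
   accumulated hit counts (success probability 0.5) classify features:
   clearly-winning ones become Confirmed, clearly-losing ones Rejected
   and leave the real-side competition. With
   `two_step_correction = TRUE` (default) the p-values are
   Benjamini–Hochberg-corrected across undecided features and must also
   pass an α/iteration guard; with `FALSE`, a plain Bonferroni
   correction over the feature count is applied.

Features still undecided at `max_iter` (default 100) stay Tentative —
and Tentative never counts as selected.

**The shadow pool never shrinks.** Implementations of this family
commonly rebuild shadows only from the not-yet-rejected features. At
n ≈ 24 that choice is anti-conservative: once the bulk of null features
is rejected, a noise feature whose *sample* correlation with the labels
happens to be large (|r| ≈ 0.5 is typical for the best of 20 features at
this n) competes against an ever-weaker shadow maximum and gets
confirmed at a high rate — we measured 1.2–1.4 false confirmations per
run on pure-noise 20-feature panels. Rebuilding shadows from the full
feature set keeps the shadow maximum an estimate of the *largest chance
association among all p features*, which is the relevant null reference;
the measured false-confirmation mean drops to ≈ 0.4 while a 5-SD planted
feature is still confirmed in 100% of runs. When fewer than five
features exist, shadows are padded to five by recycling columns (each
copy independently permuted).

Defaults: α = 0.05, `perc = 100`, `max_iter = 100`, 500 trees per
internal forest (selection quality is driven by the stability scheme,
not by any single forest; 300 trees give indistinguishable selections
in our benchmarks and are used in the test suite for speed). Every
stability run logs its parameters and derived seed.

## 4. Stability validation and reliability classes

A single selector run answers "which features beat chance in *this*
data with *this* seed". `run_validation()` asks the sturdier question:
for each of the N comparison samples held out in turn, and for each of
`n_seeds` (default 5) seeds, rerun the selector on the remaining N − 1
samples. A pairwise comparison of two groups of 12 yields 5 × 24 = 120
runs; the three-group multi-class setup yields 5 × 36 = 180. Per-run
seeds are derived by hashing (base seed, seed index, held-out sample
id), so any individual run can be reproduced in isolation.

A metabolite's **retention** is the number of runs in which it was
Confirmed:

* retention = 100% → *highly reliable*;
* retention ≥ 90% (e.g. 108/120 or 162/180) → *moderately reliable*;
* otherwise *unstable*.

Both thresholds are arguments (`reliability_thresholds()`), not
constants; analyses that want a more permissive multi-class rule (e.g.
144/180 = 80%) can set `moderate = 0.8` explicitly. Runs that would
leave a class with fewer than two samples are skipped with a warning and
excluded from the denominator.

The multi-class mode feeds the selector a 3-level response directly (no
one-vs-rest decomposition), which is a stricter criterion: a feature
must help separate all groups simultaneously, so the multi-class
selection is typically a subset of the union of pairwise selections.

## 5. Evaluation statistics

For the selected set of a pairwise comparison:

* **Δ%** = 100·(x̄₂ − x̄₁)/((x̄₁ + x̄₂)/2), on raw concentrations.
  The symmetric-mean denominator makes the statistic antisymmetric in
  group order and allows |Δ%| > 100 (a metabolite all but absent in one
  group approaches ±200) — a plain percent-of-reference on positive data
  cannot exceed 100 in the downward direction, so reported magnitudes
  above 100 identify this convention. Negative values mean the
  second-listed group is lower. The formula is centralized and swappable.
* **Mann–Whitney U**, oriented as "first group greater", ties counting
  ½. The two-sided p-value is exact when both groups are small (< 50)
  and untied, otherwise a normal approximation with tie and continuity
  correction; the method used is recorded per test.
* **ROC-AUC** = max(U, n₁n₂ − U)/(n₁n₂): the direction-free probability
  that a random cross-group pair is ordered correctly, always in
  [0.5, 1]; the direction is recoverable from the Δ% sign.
* **Bonferroni flag**: p < α/m with m = the number of metabolites tested
  after QC (the whole surviving panel, not the selected subset).
* **Random forest**: 1,000 trees (`randomForest`) on the selected
  features only; reports Mean Decrease Gini per metabolite, the OOB
  error (fraction of samples misclassified by out-of-bag votes) and the
  misclassified sample ids. The multi-class pipeline run reports a
  single multi-class OOB error.
* **Within-group correlations**: Pearson r between selected metabolites
  within one group's samples; |r| ≥ 0.5 flagged regardless of p-value.

## 6. PCA

Columns are centred and scaled to unit variance, then decomposed
(`prcomp`). Zero-variance and NA-bearing metabolites are dropped with
warnings before scaling. The sign of every component is fixed by the
convention that its largest-magnitude loading entry is positive, so
scores are reproducible across runs and platforms; with all components
retained, scores × loadingsᵀ reconstructs the scaled matrix to machine
precision. The pipeline runs PCA on residuals before and after
selection, exporting two components by default (the plotted pair);
component count is configurable.

## 7. The synthetic generator

`generate_panel(sim_config(...))` draws

$$\log y_{ij} = \mu_j + \delta_{g(i),j} + \beta_{w,j}(w_i - \bar w) +
\beta_{s,j} s_i + \lambda_j f_{b(j),i} + \varepsilon_{ij}$$

and exponentiates: concentrations are positive and right-skewed, group
effects are fold changes, covariate confounding is log-linear, and
within-block correlation comes from a shared standard-normal factor per
block with loading $\lambda_j = \sigma_j\sqrt{\rho}$ and residual SD
$\sigma_j\sqrt{1-\rho}$ — always a valid correlation structure with
pairwise within-block correlation ρ on the log scale. Two QC replicate
rows are drawn from a common latent profile with log-SD
$\sqrt{\log(1+\mathrm{CV}^2)}$. A fraction of metabolites gets a
non-trivial LOD placed at a configurable marginal quantile; values below
it are *reported as-is* with the LOD recorded, matching the package's
no-imputation policy.

Defaults mirror the targeted study design the pipeline was built
around: 3 groups × 12 samples (labels ILA/ILW/IDU), 186 metabolites in
p180-like class proportions (21 AA, 40 AC, 19 BA, 1 hexose, 14 LysoPC,
76 PC, 15 SM), sex split 5/7 in the first group and 6/6 elsewhere,
carcass weight ~ N(130, 8²) kg, replicate CV 10%, planted effects on 8
metabolites per group pair with fold changes 1.5–3, covariate effects on
a random 30% of metabolites. Each planted metabolite is elevated in the
first-listed group of its pair — a breed-specific signature — so it also
shifts that group's contrasts with third groups; the returned truth
object records the *realized* fold difference for every pair, which is
what recovery should be scored against.

The fixture catalogue (`make_fixture_suite()`) pins four regimes: `null`
(no planted effects), `strong` (two groups of 12, ten metabolites at
fold 3.5–5 with log-SD 0.15–0.25, i.e. ≈ 4–6 within-group SDs — the
near-separable regime that certifies recovery), `confounded` (covariate
effects on every metabolite), and `censored` (40% of metabolites with an
LOD at the 25th percentile). Fixture seeds are part of the fixture
identity and recorded in the manifest; regeneration is byte-identical.

What the generator does **not** emulate: batch/plate effects beyond one
plate, instrument drift, non-log-normal marginals, missingness that is
informative rather than LOD-driven, and biological correlation
structures beyond block factors. Passing tests on synthetic panels
therefore certify the *machinery* (QC arithmetic, residualization,
selection error rates, scheme bookkeeping) under the stated model — not
that any real panel satisfies that model.

## 8. Problem sizes used by the tests and the acceptance script

Structural tests run on small panels (4–24 samples, 5–24 metabolites)
with reduced selector settings, since only bookkeeping is under test.
The stochastic guarantees run at the design n (12 vs 12): 20-repetition
null and planted-feature experiments with 300-tree forests, and the
full 120-run recovery on the 60-metabolite strong fixture — panel width
is kept below the full 186 because the recovery property depends on
effect size and per-group n, not on the number of null columns, and the
narrower panel keeps the 120-run experiment proportionate. The
acceptance script additionally runs QC and PCA on a full default
186-metabolite panel. Everything completes in a few minutes on one CPU.

## 9. Known limitations

* With two QC replicates the CV filter is itself noisy; it will excise a
  few well-behaved metabolites per panel. That matches single-plate
  practice but means QC retention counts are seed-dependent.
* The selector's false-confirmation rate is not zero at n = 24: a noise
  feature whose chance association with the labels rivals the best of p
  shadow permutations can survive. The stability scheme is the intended
  mitigation — such features rarely survive 120 leave-one-out runs.
* Correlated true features share forest importance, so the weakest
  member of a correlated discriminant block is the most likely to land
  in the moderately-reliable (or unstable) class rather than the
  highly-reliable one.
* Residualization on the concentration scale removes covariate effects
  estimated on a pooled sample; with 24–36 samples, chance
  covariate–group correlation transfers some group signal into the
  removed component. This is inherent to the design, not a defect, but
  it makes OOB errors on residuals worse than on raw data when such
  chance correlation is present.
* Exact Mann–Whitney p-values are unavailable under ties; the normal
  approximation with tie correction is used and flagged in the output.
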