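# metabostab

Stability-validated all-relevant metabolite selection for targeted
metabolomics panels.

## The problem

Targeted metabolomics panels (Biocrates p180-style kits) quantify a fixed
set of ~180 metabolites — acylcarnitines, amino acids, biogenic amines,
hexoses, lyso-/phosphatidylcholines, sphingomyelins — as absolute plasma
concentrations. A recurring study design in animal science and biomarker
work compares such profiles between a few groups (here: pig breeds, e.g.
Italian Landrace / Large White / Duroc, 12 animals each) and asks which
metabolites *reliably* discriminate the groups once technical artefacts
and known covariates are dealt with.

With n = 12 per group and p ≈ 180 features, single-shot feature selection
is fragile: a selector rerun with another random seed, or with one animal
removed, can return a different list. `metabostab` implements a pipeline
that makes that instability measurable and uses it as the selection
criterion:

1. **QC filtering** — per metabolite: replicate coefficient of variation
   (CV > 20% excludes), concentrations below the limit of detection (LOD)
   across QC replicates, below-LOD rate over samples (> 30% excludes),
   NA/zero rate; plus an advisory outlier-sample screen (robust z of the
   distance from the centroid in unit-variance-scaled space).
2. **Covariate residualization** — per metabolite, ordinary least squares
   over the pooled samples, `y_i = β0 + βw·w_i + βs·s_i + ξ_i` (w =
   carcass weight, s = sex contrast); residuals `ξ̂_i` feed everything
   downstream.
3. **All-relevant selection** — a shadow-feature random-forest wrapper
   (Boruta-type): each iteration appends a permuted "shadow" copy of every
   feature, fits a forest, and scores a *hit* for a real feature whose
   Gini importance beats the shadow maximum; binomial tests on hit counts
   (p = 0.5, two-step correction) drive features to Confirmed or Rejected.
4. **Stability validation** — the selector is rerun for every
   (held-out sample × seed) pair: 5 seeds × leave-one-out = 120 runs for a
   24-sample pairwise comparison, 180 for the 36-sample three-class setup.
   Metabolites Confirmed in 100% of runs are *highly reliable*, in ≥ 90%
   *moderately reliable*, otherwise unstable.
5. **Evaluation** — per selected metabolite: relative concentration
   difference Δ% = 100·(x̄₂ − x̄₁)/((x̄₁ + x̄₂)/2) on raw concentrations,
   Mean Decrease Gini from a 1,000-tree forest, ROC-AUC
   (= U_max/(n₁·n₂), the normalized Mann-Whitney statistic), Mann-Whitney
   U tests with Bonferroni correction at α/(number of post-QC
   metabolites), within-group Pearson correlation screens (|r| ≥ 0.5
   flagged); plus the forest's out-of-bag (OOB) error.
6. **PCA** — on unit-variance-scaled residuals before and after
   selection, to show how much group separation the selected subset
   concentrates on PC1.

A synthetic panel generator with planted ground truth (`sim_config()`,
`generate_panel()`) reproduces the statistical structure the pipeline
assumes — log-normal concentrations, covariate confounding, correlated
metabolite families, QC replicate pairs, LOD censoring — so every stage
is testable end to end without any external data.

## Worked example

Generate a two-breed panel with ten planted discriminant metabolites
(fold change 3.5–5), run the full pipeline, and evaluate:

```r
library(metabostab)

cfg <- sim_config(n_groups = 2, n_per_group = 12, n_metabolites = 60,
                  n_discriminant = 10, effect_size_range = c(3.5, 5),
                  log_sd_range = c(0.15, 0.25), block_sizes = rep(6L, 4),
                  seed = 202)
gen <- generate_panel(cfg)
qc  <- apply_filters(gen$panel)
res <- fit_and_residualize(qc$panel)
cmp <- comparison_spec(c("ILA", "ILW"))
st  <- run_validation(res, cmp,
                      params = boruta_params(n_trees = 300, seed = 11),
                      n_seeds = 5)
ev  <- evaluate_comparison(qc$panel, res, st, cmp, seed = 11)
print(ev)
```

```
StabilityReport [ILA-ILW]: 120 runs
highly_reliable=9, moderately_reliable=1, unstable=45
EvaluationTable [ILA-ILW]: 10 selected metabolites
OOB error: 16.7% (4 misclassified)
   metabolite delta_percent       mdg       auc        mwu_p
1      SM_004     -121.8838 1.6884400 0.9513889 3.328210e-05
2      PC_022     -128.3960 1.6520991 0.9375000 7.174142e-05
3      AC_002     -124.7660 1.3359636 0.9583333 2.218807e-05
...
```

All ten planted metabolites are recovered (none of the 45 unselected ones
is a planted effect). The negative Δ% values say the second-listed group
(ILW) has the lower concentrations; magnitudes above 100 are possible
because the denominator is the two-group mean. The 16.7% OOB error
reflects a chance weight–group correlation in this draw that
residualization converts into class overlap — the selection itself is
unaffected, as the AUC column (0.92–0.96 per metabolite) shows. PCA on
the selected subset then puts 87% of the variance on PC1
(`run_pca(res$residuals, metabolite_subset = reliable_set(st))`),
against 22.6% before selection.

`run_pipeline(pipeline_config(...))` chains all stages for any set of
pairwise/multi-class comparisons and writes every table (TSV) plus a
reproducibility manifest (JSON) into one directory per comparison;
`compare_runs()` intersects the selections of two runs. A YAML-driven
command-line front-end is in `inst/scripts/pipeline.R`.

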