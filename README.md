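# lumisense

Serum from different disease states subtly changes the physicochemical
environment that a chemiluminescent molecular-rotor probe experiences: its
emission decays at different rates depending on protein conformation,
hydrophobicity and the library compound co-incubated in each well. A
differential-sensing array built on this readout produces, for every serum
sample, a vector of decay half-lifetimes across a compound library — a
kinetic fingerprint that can be screened for informative compounds and fed
to standard classifiers for diagnosis (e.g. Alzheimer's disease vs healthy
controls).

`lumisense` implements the full desk-side analysis for such arrays, for
assay developers and biostatisticians:

1. **Decay kinetics.** Each well's intensity time series `I(t)` is fitted by
   unweighted nonlinear least squares to the one-phase decay model

   `I(t) = A · exp(−k t) + c`,   `T½ = ln 2 / k`,

   with amplitude `A > 0`, rate `k > 0` (per minute) and unconstrained
   plateau `c`. The half-lifetime `T½` is the sole downstream feature.
2. **Flag screening.** Compound half-lives are normalized by the
   no-compound baseline of the same sample; a compound is a *flag* when its
   ratio deviates from the across-compound mean by more than 3 × SD.
   Case/control screens score each compound as the ratio of group-mean
   normalized ratios and rank a panel by `|log score|`.
3. **Batch correction.** Under the additive model
   `x_ij = μ_i + Δ_g + ε_ij` with `Δ_HC + Δ_AD = 0` and zero-mean noise,
   the per-batch baseline is estimated per compound as
   `μ̂_i = ½ (mean over HC + mean over AD)` within the batch, and features
   are corrected as `z = x − μ̂`.
4. **Diagnostic evaluation.** Standardization, PCA, and stratified 3-fold
   cross-validation of seven classifier families (logistic regression, LDA,
   QDA, SVM, KNN, decision tree, random forest) with accuracy, precision,
   recall, F1 and rank-based AUC; 2-D LDA/QDA projections for multi-group
   views; unpaired two-tailed Student t tests for group reporting.
5. **Synthetic experiments.** A fully seeded generator emits plates of decay
   traces (or half-life matrices directly) with planted group effects, flag
   compounds, batch offsets and noise, so every stage is testable end to end
   without instrument data.

## Worked example

```r
library(lumisense)

## 1. fit one trace ---------------------------------------------------------
t <- seq(5, 180, by = 5)
fit <- fit_decay(t, 1000 * exp(-log(2) / 13.15 * t) + 40)
fit
#> One-phase decay fit: I(t) = amplitude * exp(-k t) + plateau
#>   half-life: 13.15 min   rate k: 0.05271 /min
#>   amplitude: 1000   plateau: 40   RSS: 3.534e-26

## 2. screen a small synthetic library --------------------------------------
cfg <- simulation_config(n_per_group = c(AD = 3, HC = 3), n_compounds = 24,
                         flag_compounds = 3, flag_effect = 2)
ex  <- simulate_experiment(cfg, seed = 7)
res <- screen_compounds(fit_plate(ex$records), ex$metadata, panel_size = 3)
res$panel
#> Screening panel of 3 compounds (ranked by |log score|):
#>  rank compound_id    score
#>     1       C0003 2.011109
#>     2       C0001 1.982154
#>     3       C0002 1.884521
```

The three planted flag compounds come back with scores near their true
2-fold effect.

```r
## 3. batch-correct and cross-validate a cohort ------------------------------
cfg2 <- simulation_config(flag_compounds = 12, flag_effect = 1.06,
                          t_half = c(HC = 13.15, AD = 13.15))
sim <- simulate_feature_matrix(cfg2, seed = 7)      # 31 AD vs 37 HC
Z   <- correct_batches(sim$features, estimate_batch_baselines(sim$features))
cross_validate(Z, spec = classifier_spec("rf", npc = 10, seed = 7))
#> 3-fold cross-validated rf (nPC=10, seed=7, positive=AD)
#>   accuracy 89.65%  precision 85.48%  recall 93.33%  F1 89.13%  AUC 92.12%
```

Metrics are fold averages; with a subtle planted effect (6% half-life shift
on 12 of 96 compounds) the random forest recovers the group structure well
above chance. `sweep_models()` repeats this over families and nPC grids and
ranks the winners.

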