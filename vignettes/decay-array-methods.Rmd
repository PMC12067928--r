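---
title: "Methods: decay-kinetic array analysis from plate to classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decay-kinetic array analysis from plate to classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumisense)
```

`lumisense` turns plate-level chemiluminescence time series into a disease
classification through four stages — decay fitting, flag screening, batch
correction, cross-validated classification — plus a synthetic generator
that makes every stage testable. This vignette documents the models, the
parameters that matter, the numerical choices, and the design decisions
that were genuinely open.

## The decay model and its fitting

Each well is modelled as a single-exponential decay to a plateau,

$$I(t) = A\,e^{-k t} + c, \qquad T_{1/2} = \ln 2 / k,$$

with amplitude $A$ (arbitrary detector units, constrained $\ge 0$), rate
$k$ (per minute, $> 0$) and plateau $c$ (unconstrained in sign — detector
baselines can dip below zero). A single half-lifetime per curve is the
working assumption of the whole pipeline; bi-exponential kinetics are out
of scope, and intensity-derived features (peak signal, plateau level) are
deliberately not used downstream even though the fit reports them.

Fitting is unweighted nonlinear least squares via Levenberg–Marquardt
(`minpack.lm`), with an analytic Jacobian. Weighted schemes such as
$1/Y^2$ are common in plate-reader software but unweighted residuals are
the simplest defensible default when the noise model is unknown; this is a
documented choice, not an inference.

Numerical choices:

* **Initialization** is derivative-free and robust: $c_0 = \min I$,
  $A_0 = \max I - \min I$, and $k_0$ from the log-linear slope of the
  first half of the background-subtracted trace, falling back to
  $\ln 2 / (\text{range}/4)$ when that slope is unusable.
* **Convergence** uses a relative tolerance of $10^{-10}$ on the sum of
  squares (and on the parameters), with at most 10,000 function
  evaluations; both are recorded in `decay_control()` and attached to
  every fit.
* **Degenerate inputs**: traces with fewer than 4 points, non-finite
  values, or zero intensity variance (a flat curve, for which the rate is
  not identifiable) are errors. An optimizer breakdown on a usable trace
  is *not* an error: the fit is returned with `converged = FALSE` and the
  optimizer message, and `fit_plate()` propagates such wells as
  unconverged rows rather than aborting a plate.
* Replicate wells are fitted independently; half-lives (not curves) are
  averaged at the screening stage, which preserves per-replicate
  diagnostics.

On noiseless model-generated traces the fitter recovers parameters to
relative error below $10^{-6}$ across rates $k \in [10^{-3}, 1]$ per
minute on the default 5–180 min grid; the test suite verifies this, along
with agreement with an independent one-dimensional grid-search oracle on
noisy traces (the amplitude and plateau are profiled out linearly, so the
oracle scans only $k$, at $10^{-4}$ resolution).

## Flag screening

For sample $s$, compound $c$, the normalized ratio is
$T_{1/2}(s, c) / T_{1/2}(s, \text{baseline})$, where the baseline is the
mean half-life of the sample's no-compound wells (sentinel compound id
`BASELINE`). Flags are called per plate: with ratios $r_1, \dots, r_m$
across compounds, the centre is their mean, the threshold $3 \times$
their sample ($n-1$) standard deviation, and compound $c$ is flagged when
$|r_c - \bar r| > 3\,\mathrm{SD}$. Two conventions here were open and are
fixed as follows:

* the **centre** of the rule is the plain mean across compounds (robust
  alternatives like the median would be defensible but are not the
  simplest reading of a "3 × SD" rule);
* the **SD** is taken across compounds, not across replicates — replicate
  variation has already been absorbed by averaging.

If all ratios coincide the SD is zero and nothing is flagged; this is a
defined outcome, not an error. A single-compound plate is an error (SD
undefined).

The case/control screen scores each compound as the ratio of group-mean
normalized ratios (case over control). The panel ranking statistic is
$|\log(\text{score})|$, descending, with lexicographic compound-id
tie-breaks: informative compounds can lengthen *or* shorten the half-life,
and the log makes a doubling and a halving equally influential. The
ranking statistic was an open choice ("most influential" admits several
readings); the symmetric log deviation is recorded as ours.

## Batch correction

Half-life features are assumed to decompose additively,
$x_{ij} = \mu_i + \Delta_g + \varepsilon_{ij}$: a per-batch baseline
$\mu_i$ (environment, instrument), a group effect $\Delta_g$ with the
zero-sum convention $\Delta_{HC} + \Delta_{AD} = 0$, and independent
zero-mean noise. Averaging the model over the control and case index sets
of a batch and using the zero-sum convention cancels both $\Delta$ terms,
giving the estimator

$$\hat\mu_i = \tfrac12\left(\overline{x}^{\,HC}_i + \overline{x}^{\,AD}_i\right),$$

applied per compound (each compound is an independent feature). The
corrected feature is $z_{ij} = x_{ij} - \hat\mu_i$. Consequences the test
suite exercises: with $\varepsilon \equiv 0$ and balanced additive group
effects the planted baselines are recovered *exactly*, for arbitrary
offsets; the correction never changes within-batch differences between
samples; and the estimator's mean absolute error shrinks as per-batch
group sizes grow.

Two design points were open:

* **Batches without both anchor groups are rejected by name** — the
  estimator is undefined there. Samples from non-anchor groups (MS, DB,
  RA, AD-MCI) are corrected using the anchor-estimated baseline of their
  batch.
* **Estimation and application are split** (`estimate_batch_baselines()` /
  `correct_batches()`) so a model fitted on training folds *could* be
  applied to held-out data. The default workflow corrects the full matrix
  before cross-validation, matching the natural preprocessing order
  (correction, standardization, PCA, CV); users worried about leakage can
  correct within folds by composing the two functions themselves.

The expectation argument behind $\hat\mu_i$ treats the within-batch noise
means as vanishing; under strong group imbalance within a batch the
estimator inherits a bias of order the group-mean noise difference. This
is documented, not resolved — the estimator is used exactly as defined.

## Classification

`cross_validate()` runs stratified k-fold CV (default $k = 3$, read as
"3 iterations": each fold serves once as the test set and the three fold
metrics are averaged arithmetically; a `repeats` argument supports
repeated CV but defaults to 1). Folds are assigned per class by seeded
shuffle and cyclic filling, so per-fold class counts deviate from balance
by at most one sample. Standardization (mean 0, sample SD 1; zero-variance
features dropped with a warning) and PCA are fitted on the training folds
and applied to the held-out fold by default; a `preprocess = "full"`
variant fits them once on the whole matrix, closer to a
preprocessing-first reading but leakage-prone, and both are reported
explicitly in the result object.

Seven families are supported with fixed, recorded hyperparameters:
logistic regression (`glm`), LDA and QDA (`MASS`), SVM (`e1071`, radial
kernel, cost 1), KNN (`class`, $k_{nn} = 5$), decision tree (`rpart`,
cp 0.01), random forest (`randomForest`, 500 trees). Threshold metrics
(accuracy, precision, recall, F1) use each model's native label
predictions; AUC uses its continuous score — posterior probabilities
where available, the decision function for SVM — via the rank
(Mann–Whitney) statistic with ties averaged, which equals the trapezoidal
ROC area and is verified in the tests against brute-force pair counting.
The **positive class is the case group (AD)** for precision/recall/F1;
this was unstated and the clinically natural choice. Precision is defined
as 0 when no positives are predicted.

`sweep_models()` evaluates a families × nPC grid, picks per family the
nPC maximizing mean AUC (smallest nPC on ties), and ranks families by that
AUC; whether a published nPC-per-model table was chosen this way is
unknowable from the outside, so the maximization rule is simply recorded.
Multi-group comparisons use `project_2d()` (top two LDA discriminants,
zero-padded when only one exists; or the first two QDA log-posterior
contrasts against the first group) plus `group_difference_test()`
(classical unpaired two-tailed equal-variance t test, significance
annotated at $P \le 0.05$); these views are descriptive and not optimized
for classification.

## The synthetic generator

`simulation_config()` fixes the generative model: for sample $j$ of group
$g$ in batch $i$ and compound $c$,

$$T = T_{\text{base}}(g)\cdot e(c, g)\cdot e^{\varepsilon} + \delta_g + \mu_i,
\qquad \varepsilon \sim N(0, \sigma_{\log}^2),$$

traces emitted as $A e^{-\ln 2\, t / T} + c_0$ with multiplicative
Gaussian intensity noise. Defaults, chosen once as the study conditions
the pipeline is meant for:

* cohort 31 case / 37 control samples (the two published cohort figures
  disagree — 31/31 in one place, 31/37 in another; 31/37 is used), in 2
  batches with additive offsets of ±1 min; 96 compounds (up to 1024);
  triplicate wells;
* group baselines $T_{\text{base}}$: control 13.15 min (healthy-serum
  kinetics) and case 11.18 min — cases decay *faster*, the direction
  observed for AD serum; the 15% magnitude is a choice, since no
  per-compound effect sizes are published;
* 12 flag compounds at a 2-fold multiplicative effect in the case group;
  a `balanced_flags` mode splits the effect symmetrically in log space
  ($\sqrt f$ vs $1/\sqrt f$) so planted log effects sum to zero;
* $\sigma_{\log} = 0.05$ on the half-life, 2% multiplicative trace noise,
  amplitudes uniform on [800, 1200] a.u., plateaus on [20, 60] a.u.;
* acquisition grid 5–180 min every 5 min (36 points; the acquisition
  step is not dictated by the assay description, 5 min is the generator's
  documented choice).

Group effects are multiplicative on the half-life (log-additive — the
natural scale for a positive kinetic quantity), while batch offsets are
additive, matching the correction model. The additive per-group `group_delta`
(default 0) exists because the batch estimator's exactness limit is
additive with zero-sum effects; the exactness tests run in that mode.
All randomness flows from one seed; the same seed reproduces emitted
files byte for byte. Configurations that would produce a non-positive
half-life anywhere are rejected before emission.

What the generator does **not** emulate: non-exponential kinetics,
heteroscedastic detector noise, plate-position (edge) effects,
compound–compound interactions, missingness, or any real biochemical
effect-size spectrum. Passing tests therefore demonstrate that the
pipeline recovers the structure *it assumes*, at the configured effect
and noise levels — not that real serum arrays satisfy those assumptions.

## Problem sizes used by the test suite

Statistical tests run at deliberately modest sizes chosen to make their
expectations sharp: the null and planted-effect CV checks use the default
31/37 cohort over 30 seeds on the fast feature-level path; the panel
recovery check runs the full trace-level pipeline (simulate → fit →
screen → rank) at the screening-arm size of 3 cases vs 3 controls with
the default 96-compound triplicate plates over 50 seeds; the
effect-size monotonicity check uses 15/15 samples, 24 compounds and noise
multipliers {0, 2, 6} × $\sigma_{\log}$ over 12 seeds, where the ordering
of mean AUCs is decisively outside Monte-Carlo noise.

## Interface

The package's surface is its R functions — a fitting function returning a
classed model object with the usual methods, plus classed results with
print methods for each pipeline stage — together with this vignette; no
shell entry point is shipped, and `scripts/acceptance.R` is a thin
reproduction script over the installed package.

## Known limitations

* The decay model is strictly single-phase; wells with genuinely
  bi-exponential decay will fit poorly and should be screened via `rss`.
* $\hat\mu_i$ is biased under strong within-batch group imbalance (above).
* QDA requires more samples per group than features; the projection
  function fails with a pointer to LDA rather than regularizing.
* The classifier comparison is a measurement harness, not an AutoML
  search: hyperparameters are fixed defaults on purpose, so family
  rankings reflect those defaults.
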