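---
title: "Perturbation-theory moving-average models of ruminant growth yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-theory moving-average models of ruminant growth yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmayield)
```

## The problem and the model

Kid goats develop from suckling (pre-rumination, d 0-14) through a
transition (d 28-42) into full rumination (d 56-70), and from d 28 they are
managed either with supplemental concentrate feeding (S) or on pasture (G).
Along the way the mRNA expression of *Ghrelin* (an appetite/energy-
homeostasis hormone, highest in the abomasum, the ruminant "true stomach")
and of the growth hormone receptor (*GHR*) changes strongly across the
eight gastrointestinal segments (rumen, abomasum, duodenum, jejunum, ileum,
cecum, colon, rectum), with age, and between feeding systems. The question
the package addresses: can the growth yield of an animal — here the
dressing ratio, carcass weight over live weight, a number in (0, 1) — be
predicted from those expression profiles?

The modelling idea is a perturbation-theory (PT) decomposition. Every
sample sits in a condition triple $\zeta = (s, t, m)$: segment, postnatal
day, feeding system. For a gene $g$ and a condition class $c$, the
moving-average (Box-Jenkins) operator
$\langle V_g(\zeta)\rangle_c$ is simply the mean expression over all
samples sharing one level of that class; the perturbation
$\Delta V_g(c) = V_g - \langle V_g \rangle_c$ measures how far a sample
deviates from the class-level expectation. Prediction then starts from an
*expected* yield under reference conditions, $Y_{exp}$ (the mean yield of
samples sharing the reference condition triple), and adds corrections:

$$Y_{pred} = e_0 + a_0\,Y_{exp} + \sum_g a_g V_g
  + \sum_g \left[ b_g \Delta V_g(s) + c_g \Delta V_g(t) + d_g \Delta V_g(m)\right]$$

Cases are built pairwise: a *query* sample supplies the expressions and the
observed yield (the target); a *reference* sample supplies the expectation
$Y_{exp}$ and, under the default *reference-anchored* scheme, the condition
levels at which the MA operators are evaluated. The published five-feature
linear surface uses $(Y_{exp}, V_1, \Delta V_2(s), \Delta V_2(t),
\Delta V_2(m))$; `pair_features("full")` exposes all ten terms of the
expanded equation.

### Anchoring the perturbations

The pairwise construction fixes which sample is query and which is
reference, but not which of the two anchors the $\Delta V$ terms. Both
conventions are defensible, so both are implemented:

* **reference-anchored** (default): $\Delta V_g(c) = V_g(\text{query}) -
  \langle V_g\rangle_{c=\text{level of the reference}}$. The reference
  contributes information beyond $Y_{exp}$.
* **query-anchored**: the query's own levels anchor the operators; within
  any level the perturbations then average exactly to zero, a property the
  test suite checks.

### Self-pairs

An ordered non-self pairing of 352 samples yields $352 \times 351 =
123{,}552$ cases — *fewer* than the 123,872 cases the study design calls
for, while the full grid has $352^2 = 123{,}904$. The paper-scale
construction therefore must admit self-pairs: `build_pair_dataset()`
defaults to excluding them (they are degenerate under the query-anchored
scheme), while `pipeline_config()` defaults to including them so the
published case count is reachable.

## The synthetic study generator

Real studies of this design cannot be regenerated at will, so
`generate_study()` draws studies with the same shape and a known ground
truth: 44 animals, one slaughter day each (4 animals per lactation day; 4
per system per post-split day), all 8 segments sampled per animal, 352 rows
in total. What it emulates, and how:

* **Mean structure.** Expression is drawn lognormally (sd 0.25 on the log2
  scale — roughly a 19% coefficient of variation, a typical qPCR
  between-animal spread) around the published per-cell template means
  (`template_means()`), so the simulated spatiotemporal pattern — abomasum
  Ghrelin rising ~300-fold with age, GHR declining with age and sitting
  higher under S than G — is the real one. Two published cells are exactly
  zero; the generator floors template means at 0.001 so lognormal sampling
  and the qPCR inverse stay defined.
* **Yield ground truth.** On the logit scale, an animal's yield is a linear
  form in its day-level mean log2 GHR template (weight 0.15), its
  system-level mean (0.10), and its observed mean log2 Ghrelin (0.10),
  plus animal noise (sd 0.05) and a *segment-gated step*: +0.35 when the
  animal's abomasum GHR expression exceeds the template median. The
  intercept is calibrated so the mean yield is 0.47, a realistic goat
  dressing ratio; yields land in roughly 0.42-0.63. The step is the
  planted nonlinearity — it is exactly the kind of structure a tree
  ensemble can represent and a linear model cannot, so the design gives
  random forests a *genuine* advantage rather than a lucky one.
* **qPCR layer.** `generate_qpcr()` inverts the $2^{-\Delta\Delta C_T}$
  transform: it draws beta-actin Ct values in the plausible 15-25 cycle
  range and solves for target Ct so the recorded fold changes are
  reproduced to floating point.
* **Outliers.** For filter studies, a configured fraction of sample rows
  has its yield replaced by an out-of-model constant one clean-range above
  the clean yield support — a value no fit to the majority of the data can
  explain, which is what "outlier" means to a residual filter.

What the generator does **not** emulate: qPCR plate and primer-efficiency
effects, longitudinal growth curves (each animal is observed at slaughter
only), correlated noise between genes or neighbouring segments, and any
real biological linkage between expression and yield. Passing tests
therefore demonstrate that the pipeline's machinery is correct and that its
qualitative conclusions (e.g. tree ensembles beating linear fits in the
presence of gated effects) follow from the planted structure — not that the
biological effect sizes are right.

## Descriptive statistics

`stage_summary()` averages per-(day, system) cell means within each
developmental stage — the pre-rumination stage pools the three pre-split
(lactation) days, transition and rumination each pool 2 days x 2 systems —
and reproduces the published stage-mean table entries exactly after
2-decimal rounding (which rounds half *away from zero*: 0.375 prints as
0.38). The SEM is the pooled within-cell residual SE divided by
$\sqrt{\bar n}$; on the one-value-per-cell fixture it is undefined (NA) and
published SEMs are not reproduced, since they require the raw per-animal
data. Pre-split samples carry the lactation label L and are shared by both
systems' trajectories in summaries and contrasts.

`age_trend_contrasts()` builds linear and quadratic contrasts with
`poly()` on the observation-level day vector, making the coefficient
vectors orthogonal under the actual unequal spacing (0, 7, 14, 28, 42, 56,
70) *and* the observed cell counts. `feeding_effect_anova()` replaces the
original mixed-model (REML) analysis with a two-way fixed-effects ANOVA on
the balanced post-split grid — animals are the experimental unit and appear
once each, so the random animal effect is not identifiable at this grain
and a fixed-effects decomposition partitions the same sums of squares;
this is a deliberate simplification, documented rather than hidden.

## Preprocessing and the outlier filter

Features and target are min-max normalized to [0, 1]. The default fits the
parameters on the full dataset before splitting, mirroring the original
workflow; this leaks test information into the scaling and is flagged as
such — `normalization_fit = "train"` is available and is what we would
recommend for new analyses. The 75/25 split is case-level by default (again
mirroring the original design); because pairs sharing a sample straddle
such a split, a *sample-aware* mode holds out whole samples and routes
every case touching a held-out sample to the test set. That mode is still a
partition: mixed pairs (one retained, one held-out sample) go to test, so
the guarantee is that no held-out sample ever appears in a training case.

The outlier filter drops cases whose absolute residual against the
full-data OLS fit exceeds 0.4 on the normalized scale — twice the maximum
residual of the majority of the data (0.2). For a Gaussian linear model
the Pearson residual is the raw residual, so no variance function is
applied. With 2.3% contamination planted by the generator, the filter
removes 2.2-2.3% of 123,872 cases, the same accounting as the published
123,872 to 121,056 reduction.

## The regression suite

Seven methods: OLS with the full inference block (R, R², residual SS,
regression df, overall F — the general-multilinear-regression surface),
stepwise-selected OLS (AIC/BIC, bidirectional by default), PLS, Lasso,
elastic net, a single-hidden-layer neural network, and a random forest.
Standard fits are delegated to `stats::lm`/`stats::step`, `mixOmics::pls`,
`glmnet`, `nnet` and `randomForest`; the package owns the featurization,
tuning, evaluation and comparison around them. Hyperparameter grids follow
the published sweeps — neural network size in {1, 5, 10, 15, 20, 50} with
decay in {0, 0.1, 0.001} (the alternative published decay sweep
0/0.0001/0.001/0.005 can be passed via `default_grids(nn_decay = ...)`),
random forest trees in {1, 5, 10} with mtry 1..5. The original
multilayer-perceptron topologies from commercial software are represented
generically by the `nnet` learner, not re-implemented bit-for-bit.

Tuning is repeated k-fold cross-validation (5-fold, 3 repeats by default;
tests and the full-scale runs use lighter settings, stated where used)
minimizing RMSE, with one fold assignment shared across methods and grid
rows so that per-fold RMSEs are paired. Those resamples feed
`compare_models()`: paired two-sided t-tests per model pair, p-values
Bonferroni-multiplied by the number of pairs, confidence limits at the
Bonferroni-adjusted level. A zero-variance difference is flagged degenerate
(p = 0 if the means differ, p = 1 if the vectors are identical) instead of
raising an error. Every stochastic learner is seeded per (method, fold),
making whole runs byte-reproducible — the report writer exploits this for
its idempotence guarantee. The best model is the one maximizing test R²,
ties broken by lower test RMSE, then method name.

Numerical conventions worth stating: $R = \sqrt{\max(R^2, 0)}$ for
reporting parity; rank-deficient OLS designs are rejected with the
collinear columns named rather than silently aliased; an intercept-only
stepwise result is returned as a valid fit with zero features; MA tables
satisfy exact conservation (count-weighted level means equal the grand
mean), which doubles as a cheap integrity check on the featurization.

## Problem sizes used in the shipped runs

The test suite exercises the full 352-sample, 123,872-case scale for the
determinism and filter-accounting checks (with the model list restricted
to OLS + random forest and single-point grids there), and 1,500-10,000-case
pair datasets elsewhere; the model-ordering study uses 3,000 cases per seed
over 10 seeds. These sizes were chosen so each property is tested at the
scale where it is informative while the whole suite stays quick to run.

## Known limitations

* The yield definition (carcass/live dressing ratio) is the natural (0, 1)
  growth-yield index consistent with the observed RMSE magnitudes, but the
  original yield formula is not recoverable from the source material; an
  externally supplied `yield` column overrides the derivation.
* With random pairing, the reference-anchored $Y_{exp}$ carries no
  information about the query's yield in the synthetic ground truth; the
  strong $Y_{exp}$ importance reported for the original data is therefore
  not reproduced by default simulations (a dominant-feature scenario is
  exercised separately in the tests).
* Case-level splits leak sample identity across train/test; the
  sample-aware mode exists precisely because of this, and the two can give
  noticeably different test scores.
* REML mixed models, qPCR efficiency correction and multiple-testing
  control across summary cells are out of scope.
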