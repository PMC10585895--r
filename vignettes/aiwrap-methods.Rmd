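---
title: "Surrogate-assisted wrapper feature selection: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted wrapper feature selection: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiwrap)
```

## The problem

Wrapper feature selection scores a candidate feature subset by the predictive
performance of a model actually built on it. That is the most direct way to
judge a subset, but in high-dimensional regression it is ruinously expensive:
an evolutionary search over subsets wants thousands of candidate evaluations,
and each one costs a cross-validated model fit.

AIWrap replaces most of those fits with a *performance prediction model*
(PPM): a random-forest regression trained on pairs of (binary feature-membership
vector, measured performance). The wrapper's search then runs on predicted
performance, and only candidates whose prediction looks competitive are
validated with a real fit. The validated results flow back into the PPM's
training table, so the surrogate sharpens as the search converges.

The full pipeline has four stages:

1. **PPM construction.** Sample `k = 15 p` random subsets (subset size uniform
   on `1..p`, then a uniform draw of that size), fit a 10-fold cross-validated
   LASSO on each, and record its CV RMSE `c`. The table of (mask, c) rows is
   `D_perf`; a random forest (500 trees, `mtry = p/3`) regresses `c` on the
   mask bits.
2. **Coarse wrapper search.** A binary-mask genetic algorithm (tournament
   selection of size 3, uniform crossover with probability 0.8, per-bit
   mutation `1/p`, elitism 1) searches the subset space. Candidates are scored
   by the PPM; those whose predicted RMSE reaches the best quartile of all
   known true performances get a real fit, `D_perf` grows, and the forest is
   retrained once per generation. The best *validated* subset ever seen is
   `q_wrap`.
3. **Embedded selection.** `q_wrap` is expanded with all two-way products
   `xi:xj` (`m(m-1)/2` columns for `m` base features, computed from the raw
   columns) and a 10-fold CV LASSO selects `q_embed` — the nonzero support at
   the CV-minimizing penalty. This fitted model is the **AIWrap-L** predictor.
4. **Performance-based filter** (variants **AIWrap-LLr** / **AIWrap-LR**).
   For each feature `l` in `q_embed`, `B = 100` bootstrap ridge models are fit
   without `l` and scored by out-of-bag R²; the coefficient of variation
   (sd/mean) of those B values is `l`'s importance — a large value means the
   fit destabilizes when `l` is absent. A genetic algorithm over the finite
   grid of score midpoints picks the cutoff whose kept set maximizes mean
   bootstrap OOB R², ties broken toward the smaller set. The final model is
   OLS (`LLr`, when the set is smaller than `n`) or CV ridge (`LR`).

The **Standard Wrapper (StW)** baseline is the same genetic algorithm with a
real fit for every candidate and no surrogate; with the surrogate bypassed,
the AIWrap engine reproduces StW's trace exactly, which the test suite checks.

## What "performance" means here

The performance `c` of a subset is the 10-fold cross-validated RMSE of a LASSO
fit on its columns, computed on training data only. CV RMSE (rather than
training RMSE) is used because every penalized fit in the pipeline already
tunes its penalty by 10-fold CV and the test set must stay untouched by
selection. Within one pipeline run a single seeded fold assignment is shared
by every fit, so any two subsets are compared on identical splits; without
that, the fitness landscape is dominated by fold noise and the search chases
lucky splits rather than better subsets.

One practical consequence of CV-RMSE fitness is a plateau: once a subset
contains all informative features, adding a noise feature barely changes the
LASSO's CV RMSE (the penalty zeroes it), so the search distinguishes such
subsets only weakly. The coarse stage therefore reliably *contains* the
signal but usually carries a few noise features — which is exactly why the
embedded and performance-based stages exist.

## The simulation generator

`standard_scenarios()` defines seven study conditions. Features are
multivariate standard normal with a compound-symmetry correlation of 0.5
among the first `min(15, p)` features; the outcome is

$$y = \beta_0 + \textstyle\sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j + \varepsilon,
\qquad \varepsilon \sim N(0, 0.25^2),$$

with alternating coefficients ±0.5 on the first ten features and, in the
interaction scenarios, on the nine adjacent pairs `x1:x2 … x9:x10` (both
sequences start at +0.5). Marginal scenarios use p = 50 or 100 with 50–100
training samples; interaction scenarios use p = 15/25/50 with 100 training
samples; every test set has 500 samples. The intercept defaults to zero: all
described effects are slopes.

Two generator choices deserve a note. First, the within-block correlation is
0.5. Second, the interaction scenarios train on 100 samples: with ten
marginal and nine interaction coefficients of magnitude 0.5 plus the
correlated block, 50 samples put even the true-support OLS oracle far above
the noise floor, whereas at n = 100 a standalone cross-validated LASSO on the
full two-way expansion already performs at the level such a baseline should
achieve on this design — so 100 is the coherent training size for those
scenarios.

What the generator does *not* emulate: non-Gaussian or heavy-tailed features,
heteroscedastic noise, higher-order interactions, and realistic correlation
structures beyond one exchangeable block. Passing the simulation suite
therefore says the machinery works under the stated design, not that the
method's error rates transfer to any particular real dataset.

## Numerical and design choices

* **Penalty paths.** All penalized fits use the standard 100-value log-spaced
  glmnet path with the penalty chosen at minimum 10-fold CV MSE; "selected"
  means |coefficient| > 1e-8 on the original scale. Interaction columns are
  built from raw features and the whole augmented design is standardized
  inside the fit, preserving product semantics while keeping the penalty
  fair.
* **Single-feature subsets** are fit by least squares with the same seeded
  folds (a CV-tuned penalty over one standardized column adds nothing at the
  subset-scoring stage, and the path solver needs two columns).
* **Adaptive ridge** uses per-feature penalty weights `1/(|b_ridge| + 1e-6)`
  from a preliminary CV ridge fit, exponent 1.
* **Surrogate.** 500 trees, `mtry = p/3`, bootstrap resampling, scratch
  retrain each generation on the deduplicated `D_perf` (duplicate masks keep
  their first recorded performance). Tree ensembles cannot extrapolate beyond
  the training performance range, which is harmless here because only the
  *ranking* of candidates feeds the gate.
* **Validation gate.** The 25th percentile (linear interpolation) of all known
  true performances. If no candidate passes, the generation's best-predicted
  candidate is force-validated so a validated optimum always exists.
* **Importance direction.** Removing feature `l` and seeing the bootstrap OOB
  R² become *unstable* (high CV of R²) marks `l` as important; a non-positive
  mean R² after removal is treated as catastrophic (infinite importance,
  always kept). The cutoff grid is the set of midpoints between consecutive
  distinct scores plus the keep-all cutoff, and — when infinite scores exist —
  one cutoff above all finite scores so the minimal always-kept set is
  reachable.
* **Bootstrap economics.** The leave-one-out refits reuse a single CV-chosen
  ridge penalty (chosen once on the full `q_embed` design), and all candidate
  cutoffs are evaluated on one shared set of bootstrap resamples; both choices
  remove nuisance variance from comparisons and cut cost by an order of
  magnitude.
* **Seeding.** One master seed derives all stage seeds
  (`derive_seeds()`), giving bit-identical reruns; the audit counter
  `fit_count()` makes the surrogate's fit economy checkable from outside.
* **Degenerate inputs.** Empty feature sets yield intercept-only models with a
  warning; constant outcomes short-circuit to intercept-only; empty GA
  offspring are repaired by activating one random bit; a stage that selects
  nothing falls back to the previous stage's set with a warning.

## Problem sizes used in the shipped checks

The replicated-study harness defaults to ten trials. The package's own
acceptance script runs the interaction scenarios at desk scale — eight trials
of `1_I` and four of `2_I` with a GA budget of 30 × 40
(population × generations), and the full ten trials for the standalone-LASSO
baseline — sizes chosen so a complete rerun stays in the minutes range on one
CPU while the replication noise stays within the stochastic tolerances. The
test suite uses smaller budgets still wherever search quality is not the
property under test.

## Known limitations

* The CV-RMSE fitness plateau means the coarse stage rarely prunes *all*
  noise features; final precision rests on the embedded and filter stages.
* Published summaries of this design report a mean selection F1 for the
  interaction scenarios that is hard to reconcile with the same study's
  reported selected-feature counts (with ~46 selections against 19 targets,
  perfect recall caps F1 at ≈ 0.59); our replication lands at the cap, not
  above it.
* The surrogate needs `D_perf` rows that resemble the subsets the GA visits;
  with very small `p` the subset space is tiny and the forest sees few
  distinct masks (handled, but the surrogate adds little there).
* Continuous outcomes only; binary, longitudinal and time-to-event outcomes
  are out of scope.
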