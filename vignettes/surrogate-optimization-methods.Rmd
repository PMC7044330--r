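---
title: "Surrogate-based optimization of culture conditions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-based optimization of culture conditions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultopt)
```

## The problem

Plant tissue-culture outcomes — here, the differentiation rate of melon
calluses into plantlets — depend jointly on environmental factors such as
agar concentration, photoperiod, temperature and relative humidity. Running
a wet-lab experiment for every candidate combination is infeasible, so the
standard strategy is: (1) run a small designed experiment, (2) fit a cheap
predictive model (a *surrogate*) of the response, and (3) optimize the
surrogate instead of the biology. `cultopt` implements this workflow with a
small feedforward neural network as the surrogate and a real-coded genetic
algorithm (GA) as the optimizer, alongside the classical response-surface
methodology (RSM) baseline.

The shipped dataset ([`load_table1()`]) is a 31-run five-level four-factor
central composite design (CCD): a $2^4$ factorial core at coded levels
$\pm 1$, eight axial runs at $\pm 2$, and seven center replicates. Each
factor's coded level $c$ maps affinely to actual units,
$\mathrm{actual} = \mathrm{center} + c \cdot \mathrm{step}$
(0.6 % + 0.1 %/unit for agar, 12 h/d + 2, 28 °C + 4, 70 % RH + 10). The
coded scale is the package's internal currency; actual units appear only at
I/O boundaries, because the GA bounds and the RSM polynomial are both
defined on coded factors. Row order in `build_ccd()` (factorial, then
axial, then centers) is a package convention chosen for diff-stable
fixtures — no run order is implied by the data source, and none matters
statistically here.

The response is a percentage computed from counts,
$P = (\omega_0 - \omega_1)/\omega_0 \times 100$, with $\omega_0$ inoculated
calluses and $\omega_1$ calluses forming plantlets
(`differentiation_rate()`). That labeling arguably describes the
*complement* of plantlet formation; the package implements the formula
exactly as conventionally printed and exposes `plantlet_rate()`
($\omega_1/\omega_0 \times 100$) for users who want the other reading.

## The surrogate: a 4-h-1 backpropagation network

The network has one hidden layer with tan-sigmoid activation
($\mathrm{tansig}(z) = 2/(1+e^{-2z}) - 1 = \tanh z$) and a linear output:

$$\hat y(x) = W_2 \tanh(W_1 x + b_1) + b_2.$$

Inputs and targets are linearly rescaled to $[-1, 1]$ per variable from
their observed ranges (`fit_scaler()`); predictions are mapped back before
any metric is computed. This normalization is not part of the scientific
model — it simply keeps the tanh units out of saturation on raw percent or
degree scales — but it must be fitted on training data only during
cross-validation, which `cross_validate()` enforces.

Training is full-batch backpropagation of the mean-squared-error loss.
Five update rules are provided (`train_config()`):

* `gd` — plain gradient descent;
* `gdm` — adds a classical momentum term
  $v \leftarrow \mu v - \eta \nabla L$;
* `gda` — adaptive learning rate, no momentum;
* `gdx` — momentum *and* adaptive rate, the package's default and the rule
  selected for the melon data. After each epoch the new MSE is compared
  with the previous one: if it worsened by more than a factor
  `max_perf_increase` (default 1.04) the step is discarded, the rate is
  multiplied by `lr_decrease` (0.7) and momentum is suppressed for one
  step; if it improved, the rate is multiplied by `lr_increase` (1.05).
* `lm` — Levenberg–Marquardt damped Gauss–Newton on the residual Jacobian,
  much faster on these tiny problems but prone to sharp interpolation.

Defaults (learning rate 0.01, momentum 0.9, 1000 epochs, gradient-norm
floor $10^{-6}$) are the long-standing conventions for this family of
trainers; none of them is informed by the melon study, which does not
report training hyperparameters. Weight initialization is seeded and
Nguyen–Widrow-flavored: hidden rows scaled to magnitude $0.7\,h^{1/k}$
with biases spread across the active region. Every stochastic entry point
takes an explicit integer seed, and `withr::with_seed()` keeps the global
RNG state untouched.

The exact backpropagated gradient is verified in the test suite against a
central finite-difference oracle on dozens of random architectures
(relative error below $10^{-5}$) — the single most important correctness
check in the package, since every trainer consumes that gradient.

## Model selection by repeated k-fold cross-validation

Two nested choices are selected by repeated k-fold CV scored with held-out
MSE (`cv_plan()`, default $k = 10$ repeated 10 times, fresh shuffled
partition each repeat):

1. the training rule, compared at a fixed hidden width of 6
   (`select_training_function()`);
2. the hidden width over 1–15 with the winning rule
   (`select_hidden_size()`).

The melon study's own account is internally inconsistent about $k$ (five
vs. ten) and about the width range (1–15 vs. 1–20); the package defaults
to $k = 10$ and 1–15 and leaves both configurable rather than adjudicating.
Held-out MSE is reported on the proportion scale (rates divided by 100) —
the same convention under which the study's headline RMSE of 0.0108 arises
from percent-valued data — with `scale = "percent"` available. A fold whose
training diverges is scored with the training-target variance (the
predict-the-mean baseline) rather than aborting the whole selection; this
keeps a single pathological initialization from discarding a candidate, and
divergent folds are counted on the result object.

With 31 data points, ten-fold CV of a 19-parameter network is noisy; the
selected width on the real data varies between small values across seeds.
That is an honest property of the procedure at this sample size, which is
why the headline pipeline can also be run with the selection stages skipped
and the final 4-3-1/`gdx` configuration pinned.

## The final surrogate and the GA

`fit_bp_surrogate()` trains on *all* rows with best-of-`restarts` seeded
initializations (default 10), selected by final training MSE. Restarting is
the package's mitigation for bad random starts; how the original study's
deployed network was produced after CV is not documented, so training on
all rows is the natural choice for a deployment model.

`run_ga()` maximizes any black-box fitness over a box. The melon settings
— population 20, crossover probability 0.8, at most 100 generations,
floating-point chromosomes — are fixed by the study; the remaining
operators are unstated there and default to standard real-coded practice:
tournament selection of size 2 (roulette available), arithmetic crossover
with a uniform blend weight, per-gene Gaussian mutation (probability 0.1,
sd 0.2 coded units, clipped to bounds), and two elites. With at least one
elite the per-generation best-fitness history is non-decreasing, which the
tests assert. The search box defaults to the coded $[-2, 2]^4$ design box:
the published optimum includes coded-$\pm 2$ levels (agar 0.8 %, light
8 h/d, 20 °C), so the search space must cover the axial range, not just the
factorial cube. Convergence typically occurs within ~15 generations; the
configured budget is still run to completion and the full history recorded.

## The RSM baseline

`fit_full_quadratic()` fits the standard 15-term second-order polynomial
(intercept, 4 linear, 4 pure quadratic, 6 pairwise interactions in fixed
lexicographic order) by OLS via `stats::lm()` on coded factors, and
`maximize_quadratic()` finds its box-constrained maximum by a dense grid
plus an L-BFGS-B polish. On the shipped data this reproduces the published
fit closely but not digit-for-digit: the refit gives $R^2 = 0.8776$ and
predicts 86.06 % at the published RSM optimum (coded
$(0.8, -1, -0.625, -0.578)$), against printed values of 0.8751 and
86.04 %. The original numbers come from a different implementation
(Design-Expert), which may have used a reduced model or its own rounding;
the package deliberately fits the full quadratic because no term selection
is documented, and the acceptance tests therefore assert agreement at the
0.005 / 0.05 level rather than printed-precision equality, backed by an
exact (to $10^{-8}$) coefficient-recovery check on noiseless synthetic
quadratics through the same design.

A related caveat affects the network metrics: the published $R^2$ of
0.9637 between the dataset's actual and predicted columns is not
reproducible from those columns — their squared Pearson correlation is
0.9340 (unsquared, 0.9664) while their proportion-scale RMSE of 0.0108 *is*
exact. The acceptance suite asserts the published value and documents the
failure rather than substituting a reproducible one. (Networks trained by
this package on the same data routinely reach training $R^2$ of
0.95–0.97, suggesting the published figure described a particular trained
model rather than the printed columns.) A second published RMSE of 0.4971
appearing in a discussion passage is inconsistent with the same source's
0.0108 and is ignored.

## The synthetic-surface generator

`sample_surface_spec()` draws a concave quadratic on the coded box:
Hessian with eigenvalues in $[-3, -0.2]$ (percentage points per squared
coded unit, bracketing the curvature of the melon fit), optimum drawn
uniformly in $[-1.8, 1.8]^4$ with a 0.3 probability of being pushed to a
boundary face, peak response uniform in 80–95 %. `generate_dataset()` adds
Gaussian noise (default sd 1 percentage point, the scatter of the study's
wet-lab replicates) and clips to $[0, 100]$. `true_optimum()` returns the
closed-form stationary point $x^\star = -\tfrac12 Q^{-1} b$ when interior,
else the grid-plus-polish boundary maximum, and serves as the oracle for
end-to-end recovery tests.

What the generator emulates: a smooth, gently curved rate surface observed
with homoscedastic replicate noise on a bounded percentage scale. What it
does not: heteroscedastic or non-Gaussian error, batch effects between
experimental blocks, non-quadratic response shapes (thresholds, plateaus),
and any mechanistic biology. Passing recovery tests on these surfaces
therefore demonstrates the statistical machinery, not the adequacy of a
quadratic description of any particular organism. Recovery is asserted on
the *true-surface value at the found point*, never on the point itself:
flat optima make point recovery ill-posed while value recovery stays
meaningful.

## Known limitations

The most important one is structural and the package's tests surface it
deliberately. The CCD places all 31 points within coded radius 2 of the
center, while the corners of the $[-2,2]^4$ search box lie at radius 4. A
3-hidden-unit network pinned down only at the design points can extrapolate
toward those unsampled corners with errors of several percentage points,
and a global optimizer preferentially exploits exactly the regions where
the surrogate over-predicts (the winner's-curse bias of surrogate
optimization). In the end-to-end recovery experiment shipped in the
acceptance suite (ten seeded quadratic surfaces, 1-point noise, full
pipeline with ten restarts), the found point's true-surface value is within
2 percentage points of the true optimum in only about half the runs, and
the corresponding assertion fails; gaps of 2–5 points occur even with the
Levenberg–Marquardt trainer driving the training MSE to $2 \times 10^{-4}$,
so better optimization of the training loss cannot close them. Users should
treat a surrogate optimum at high coded radius as a hypothesis requiring
wet-lab validation — which is precisely what the melon study did, and its
own GA optimum sits at coded radius 3.6 with a validation error of 1.59 %.

Other limitations: no early stopping or regularization (the networks are
tiny and restart-selected); batch training only; the CV estimate is not
nested, so the selected model's held-out MSE is optimistically biased as a
generalization estimate; GA constraint handling is box-only.

## Problem sizes and reproducibility

The test suite runs its CV and recovery experiments at reduced sizes
(e.g. $k \in \{3,4,5\}$ folds, 1–2 repeats, 200–2000 epochs, 2–10
restarts), chosen so the whole suite completes in about a minute while
still exercising every code path; the headline real-data experiment (five
seeded pipeline runs with ten restarts each) runs at full size. All
stochastic results in the package are reproducible from explicit integer
seeds, and a pipeline report records every derived seed it used.

This package is driven from R: `run_pipeline()` /
`validate_against()` are the top-level entry points, and
`scripts/acceptance.R` in the source repository re-computes the headline
numbers from scratch; no shell CLI is shipped.

```{r example, eval = FALSE}
t1 <- load_table1()
report <- run_pipeline(t1, pipeline_config(skip_selection = TRUE,
                                           hidden = 3, trainer = "gdx",
                                           seed = 42))
report
validate_against(report, c(90.35, 89.97, 91.26))
```
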