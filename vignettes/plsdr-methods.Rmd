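---
title: "Deviance-residual PLS extensions of the Cox model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deviance-residual PLS extensions of the Cox model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsdr)
```

## The problem

Gene-expression survival studies relate a right-censored time-to-event
outcome ($t_i$, $\delta_i$) for $n \approx 100$ subjects to $p \approx 1000$
correlated predictors. A Cox proportional-hazards model
$\lambda(t \mid x) = \lambda_0(t) e^{\beta' x}$ cannot be fit directly when
$p > n$; partial least squares (PLS) supplies regularization by building a
few latent components, tolerates strongly correlated predictors, and — via
the NIPALS slope convention — copes with missing entries without prior
imputation. This package implements the PLS-based Cox families (PLSDR and
its sparse/group/kernel variants, PLS-Cox, autoPLS-Cox), the censored-data
cross-validation criteria needed to pick the number of components, and the
survival-specific performance measures used to compare those criteria,
together with three gene-expression simulators so the whole comparison can
be rerun at desk scale.

## The PLSDR pipeline

1. **Null deviance residuals.** Fit the covariate-free Cox model; the
   Nelson–Aalen cumulative hazard $\hat\Lambda_0$ gives martingale residuals
   $\hat M_i = \delta_i - \hat\Lambda_0(t_i)$, transformed to deviance
   residuals
   $d_i = \mathrm{sign}(\hat M_i)\sqrt{2\{-\hat M_i - \delta_i
   \log((\delta_i - \hat M_i)/\delta_i)\}}$,
   a variance-stabilized, approximately centered continuous surrogate for
   the censored outcome (`null_deviance_residuals()`).
2. **PLS regression of $d$ on $X$.** Standard PLS1 with NIPALS-style
   weights; per component the unit-norm weight is the pairwise-complete
   cross-product direction (exactly $X'd/\|X'd\|$ on complete data), the
   score is $t = Xw$ (with the missing-data rescaling below), loadings come
   from regression on the score, and only $X$ is deflated.
3. **Final Cox fit on the scores.** Newton–Raphson with step-halving on the
   Breslow partial likelihood; the fitted model predicts a linear risk
   score $\hat\beta' t(x)$ and survival curves
   $\hat S(t \mid x) = \exp\{-\hat\Lambda_0(t) e^{\mathrm{risk}(x)}\}$.

Sparse (sPLSDR) variants soft-threshold the direction,
$(|Z_j| - \eta\max_j|Z_j|)_+\,\mathrm{sign}(Z_j)$, the scale-free
$\eta \in [0,1)$ being the single thresholding knob; group variants
(gPLSDR) shrink whole predictor blocks by their Euclidean norms, and
sparse-group (sgPLSDR) additionally thresholds inside surviving blocks.
Thresholded directions are renormalized to unit norm before the score is
computed. Dual/kernel (DK) variants replace $X$ by a double-centered Gram
matrix (linear $XX'$ or gaussian with bandwidth defaulting to the median
pairwise distance); its $n$ columns then play the role of predictors, and
sparse DK variants threshold the $n$-dimensional dual direction. Kernel
centering is what makes the gaussian kernel converge to the linear one as
the bandwidth grows (checked in the test suite on the leading component;
later components diverge through higher-order kernel terms).

PLS-Cox builds components differently: the weight of predictor $j$ in
component $h$ is its Cox coefficient conditional on the $h-1$ previous
components (each predictor reduced to its deflation residual), so the
construction consults the partial likelihood at every step rather than
once. autoPLS-Cox zeroes the weights of predictors whose conditional Wald
$p$-value exceeds $\alpha$ (default 0.05) and stops adding components as
soon as no predictor is significant — implementing the "no predictor
significant, stop" reading of the stopping rule; the alternative "any
predictor non-significant" reading would almost always stop at zero
components and is not used. With many predictors the per-predictor 5%
test fires somewhere by chance alone ($1 - 0.95^p$), so the data-driven
component count is only conservative for modest $p$; this is a property of
the rule, not of the implementation.

## Missing data

Missingness is assumed MCAR. All weight and loading steps use
pairwise-complete cross products over complete-sample denominators: this
reduces exactly to the complete-data algorithm, leaves the fit invariant
when entries that happen to be zero are masked, and keeps the direction
unbiased under MCAR. Scores use the NIPALS rescaling
$t_i = (\sum_{j\,\mathrm{obs}} w_j x_{ij}) \cdot \sum_j w_j^2 /
\sum_{j\,\mathrm{obs}} w_j^2$, which keeps them approximately unbiased for
rows with missing entries at the cost of a small inflation of the masked
rows' scores — the two goals (exact zero-mask invariance of the scores and
unbiased prediction on incomplete rows) cannot be met simultaneously, and
prediction quality wins. The kernel path requires complete (or
mean-imputed) data.

## Cross-validation criteria

Folds are balanced: subjects are ordered status-major (status, then time),
cut into `floor(n/K)` bins of `K` adjacent subjects, and each fold draws
one subject per bin, the `n mod K` remainder spread one-per-fold. The
status-major ordering is what makes every fold's censoring rate match the
sample's (time-major ordering leaves the fold censor rates binomially
noisy). `K = 7` by default.

* **CVLL** (naive): the held-out fold's own log partial likelihood at the
  linear predictors of the fold-excluded model. Undefined for folds
  without events (excluded with a logged count).
* **vHCVLL** (van Houwelingen): $l_{\mathrm{full}}(\hat\beta_{(-j)}) -
  l_{(-j)}(\hat\beta_{(-j)})$, which uses the full-data risk sets and is
  defined for every fold. Larger is better for both; the sign convention
  follows the van Houwelingen literature.
* **Prediction-error criteria**: integrated (un)weighted Brier and Schmid
  scores of the held-out fold's predicted survival curves.
* **AUC criteria**: six integrated time-dependent AUC estimators of the
  held-out risk scores (below).

`select_hyperparameters()` fits every grid point per fold and returns the
best fold-mean; orientation (maximize vs minimize) is hard-coded per
criterion. Ties go to fewer components, then larger $\eta$ (parsimony
first). Defaults follow the benchmark's recommendation: iAUCSH for
PLS-Cox/autoPLS-Cox, iAUCsurvROC for the (DK)(s)(g)PLSDR families.

## Performance measures

IPCW prediction-error curves weight subjects by the Kaplan–Meier estimate
$\hat G$ of the censoring distribution (KM on $(t_i, 1-\delta_i)$):

* Brier $BS_w(t)$: event term $\hat S(t|X_i)^2/\hat G(t_i)$, at-risk term
  $(1-\hat S(t|X_i))^2/\hat G(t)$. The at-risk denominator follows the
  standard IPCW convention $\hat G(t)$.
* Schmid $SS_w(t)$: the absolute-deviation analogue, event term weighted
  by the left limit $1/\hat G(t_i^-)$.
* Unweighted versions clear the $\hat G$ denominators and are bounded in
  $[0,1]$; weighted and unweighted coincide exactly without censoring.

Curves are evaluated on the unique event times, integrated by
$(1/\max t_i)\int_0^{\max t_i}$ with trapezoids, extending the curve
constantly beyond its first/last grid point. The $R^2$-type summaries
divide pointwise by the Kaplan–Meier (covariate-free) reference curve:
iR2BSw from the Brier curve, and **iRSSw** — the robust
least-absolute-deviation coefficient of determination
$\int (1 - SS(t)/SS^0(t))$ — from the Schmid curve. Likelihood $R^2$s
(Nagelkerke, O'Quigley–Xu–Stare with events in place of $n$, and
Xu–O'Quigley from Schoenfeld-residual sums of squares) and three
concordance indices (Harrell's pairwise C with tied risks scoring zero,
Uno's IPCW-weighted C, and the Gönen–Heller covariate-only estimator
GHCI) complete the panel.

The six integrated AUC estimators share a cumulative/dynamic pointwise
skeleton — cases $\{t_i \le t, \delta_i = 1\}$ vs controls $\{t_j > t\}$ —
and differ in weighting: survROC and Uno weight cases by
$1/\hat G(t_i^-)$, HC by $1/\hat G(t_i)$, SH uses the plain empirical
sets, CD weights cases by their Kaplan–Meier mass, and HZ is the
incident/dynamic risk-set estimator (events at $t$ vs subjects still at
risk). CD, HZ and survROC integrate against the event-density weight
$w(t) \propto 2\hat f(t)\hat S(t)$; Uno, SH and HC integrate uniformly.
The sources the estimators are named after differ in smoothing details
beyond this package's scope; agreement with their reference
implementations is a validation activity, not a contract, but every
estimator is anchored by the 0.5-under-independence and
1-under-perfect-ranking tests, and the survROC estimator is verified
against an independent brute-force pair enumeration.

## Simulators — the stated world

All three schemes emit $n = 100$ samples of $p = 1000$ genes by default,
the first 100 structured and the rest i.i.d. N(0,1):

* **Eigengene**: 4 modules of 25 genes; gene $k$ of a module is its
  standard-normal seed plus noise scaled so that
  $\mathrm{cor}(x_k, \mathrm{seed}) = 1 - (k/25)(1 - 0.5)$, spanning 0.98
  down to 0.5.
* **Cluster**: two sample halves with means 3 vs 4 on the first 50 genes,
  3.5 on the rest, unit-variance noise.
* **Factorial**: 4 groups of 25 genes with compound-symmetry correlation
  0.7 within groups and independence across, generated through the
  symmetric square root of the block correlation matrix; the 4 leading
  directions carry 71.2% of the structured-block inertia.

Survival: $T_i \sim \mathrm{Exp}(\lambda_T e^{\eta_i})$ with $\lambda_T = 1$
(the time unit is arbitrary; every downstream measure is rank-based or
rescaled), $\eta_i = 0$ (no link) or $\beta' x_{i,1:50}$ (linear link) on
the first 50 genes with $\beta_j = 1/\sqrt{50}$, so
$\mathrm{var}(\eta) \approx 1$ — the paper prints no coefficient values, so
this unit-signal choice is the package's stated world. The quadratic link
uses $\eta = \beta'x + (\beta/2)'(x^2 - 1)$, the centered squares keeping
$E[\eta] \approx 0$. Censoring is independent exponential with rate
calibrated to a 40% censoring fraction: closed form
$\lambda_C = \lambda_T q/(1-q)$ under the null; under a link, bisection on
the exact conditional expectation
$\mathrm{mean}_i\,\lambda_C/(\lambda_C + \lambda_T e^{\eta_i})$ (tolerance
$10^{-6}$) — deterministic and strictly tighter than Monte-Carlo
calibration. MCAR masking flips each entry independently.

What a green test establishes: the pipeline recovers calibrated structure
(correlations, censoring rates, component counts) from data whose
generative model matches the working assumptions — proportional hazards,
exponential margins, MCAR missingness, independent censoring. Real
expression data violate all four to varying degrees; the simulators make
no attempt to emulate heavy-tailed expression, informative censoring, or
batch structure.

## Numerical choices

* Cox ties: Breslow (Efron available), matching the Breslow baseline used
  by the residual stage; events precede censorings in risk sets at tied
  times. Convergence at $|\Delta \log PL| < 10^{-9}$ or 50 iterations.
* Monotone likelihood: flagged when a standardized coefficient passes 50,
  or when the likelihood has plateaued while the Newton increment is still
  large (the drift signature of separation) — the second rule catches
  separations the threshold alone misses because the plateau fires first.
* Degenerate PLS directions truncate the fit at the previous component
  with a flag rather than erroring.
* $\hat G(t^-)$ is the left limit of the censoring KM step function.
* Grid points whose reference curve is zero are excluded from $R^2$
  integration with a logged count.

## Reduced-scale benchmark

`run_benchmark()` reruns the criterion comparison at desk scale: default
10 datasets per scheme-link arm (the original study used 100), balanced
7:3 train/test split, 7-fold balanced CV per criterion on the training
split, refit at the selected hyperparameters, evaluation of the
performance panel on the test set, and paired deltas against CVLL/vHCVLL.
At this scale the central finding reproduces directionally — vHCVLL
selects a median of at most one PLSDR component on factorial linear-link
data while iAUCsurvROC-selected models achieve higher median test-set
iRSSw and GHCI — which is exactly what the acceptance suite asserts; the
medians themselves are noisier than the full-scale study's.

## Known limitations

Time-dependent covariates, stratification, left truncation and recurrent
events are out of scope, as are the full three-penalty sparse-PLS
optimization (only its univariate soft-threshold solution is
implemented), PLS2, variance estimates for any measure, and out-of-core
fitting for data that do not fit in memory.
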