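---
title: "Methods: stacked survival modelling for prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked survival modelling for prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacksurv)
```

`stacksurv` implements a complete prognostic-modelling workflow for
right-censored overall survival from gene expression: correlation screening
against a seed gene panel, sparse Cox signature construction, stacking of
several sub-model linear predictors, a machine-learning final model on the
stacked predictor plus clinical covariates, and the associated
discrimination/calibration/stratification toolkit. This vignette records the
models, the numerical choices, and the reasoning behind the design
decisions that were genuinely open.

## The Cox engine

Everything model-like in the package rests on the Breslow partial
likelihood. For linear predictor $\eta_i = x_i^\top\beta$,

$$\ell(\beta) = \sum_{s}\Big[\sum_{i \in D_s} \eta_i
  - d_s \log \sum_{j \in R_s} e^{\eta_j}\Big],$$

with $D_s$ the deaths at the $s$-th distinct event time, $d_s = |D_s|$, and
$R_s$ the risk set. Breslow tie handling is used throughout and stated
explicitly, since the upstream literature is silent on ties.
`fit_cox()` maximizes $\ell$ by Newton–Raphson with step-halving (the
log-likelihood never decreases across iterations), converging when the max
absolute score falls below $10^{-8}$ or after 50 iterations, and returns the
observed-information covariance. A per-covariate ridge option stabilizes
degenerate columns; coefficients beyond $|\beta| = 15$ trigger the
monotone-likelihood guard (capped with a warning). The same module provides
a weighted-L1 solver (outer IRLS quadratic approximation, cyclic coordinate
descent with an active set, compiled in C++) whose objective is
$\ell(\beta) - \sum_j \lambda_j|\beta_j|$; columns are internally centred
and scaled, which is an exact reparametrization of this objective but
conditions the coordinate updates on raw log2 expression scales. The test
suite cross-checks both solvers against `survival::coxph` and `glmnet`,
which are never used as the implementation.

## Screening

`spearman_screen()` computes Spearman correlation as Pearson on mid-ranks
and a two-sided p-value from $t = R_s\sqrt{(n-2)/(1-R_s^2)}$ with $n-2$
degrees of freedom. A gene passes if it clears $|R_s| > 0.4$, $P < 0.05$
against **any** seed gene: the aggregation rule was unspecified upstream,
and the any-seed reading is the maximal-sensitivity one consistent with the
large reported candidate counts. No multiple-testing correction is applied
at either screen — fidelity to the raw-threshold workflow, not a
statistical recommendation. The univariate Cox screen runs on raw
log-expression by default (hazard ratios per unit log2 expression, matching
how published per-gene HRs are read); z-scoring is available behind
`standardize = TRUE`.

## Spike-and-slab lasso and the CVPL

`sslasso_select()` places a two-component double-exponential (mixture
Laplace) prior on each coefficient: spike scale $s_0$, slab scale $s_1$,
prior inclusion probability $\theta$. The EM iteration is

* **E-step**: $p_j = \Pr(\text{slab} \mid \beta_j)$ under the mixture;
* **M-step**: a weighted-L1 Cox fit with per-coefficient scale
  $S_j = (1-p_j)s_0 + p_j s_1$ and penalty $1/S_j$;

iterated to $\|\Delta\beta\|_\infty < 10^{-4}$ (at most 200 iterations).
$\theta$ is fixed at 0.5 (the uninformative default of this method family;
exposed as an argument). The default $s_0$ grid is 16 log-spaced values in
$[0.005, s_1]$ with $s_1 = 1$, spanning near-hard-thresholding to
near-unpenalized. $s_0$ is chosen by the cross-validated partial
log-likelihood in the Verweij–van Houwelingen form,
$\mathrm{CVPL} = \sum_k [\ell(\hat\beta_{(-k)}; \text{all}) -
\ell(\hat\beta_{(-k)}; \text{all} \setminus k)]$, averaged over replicated
event-stratified folds (stratification prevents event-free folds under
heavy censoring). Cross-validation fits use a looser inner tolerance than
the final fit — they only rank $s_0$ values — and warm-start along the grid
from dense to sparse. At $s_0 = s_1$ the EM collapses to a plain lasso-Cox
at fixed penalty $1/s_1$, which the acceptance suite verifies against an
independent fixed-penalty fit to $10^{-6}$.

At the CVPL-optimal $s_0$ the selected set behaves like a lasso at
lambda-min: the causal genes are captured together with weak false
positives. That is intentional — the stepwise AIC stage
(`stepwise_aic()`, bidirectional, ties broken toward the smaller model,
coefficients from the final unpenalized fit) is the stage that prunes the
signature.

## Risk score and the proportional-hazards check

`risk_score()` is the exact linear combination
$\sum_i \beta_i \mathrm{Exp}_i$ with no standardization, so the packaged
14-gene signature reproduces its published per-gene coefficients on
unit-expression patients. `ph_test()` correlates scaled Schoenfeld
residuals with Kaplan–Meier-transformed time (through
`survival::cox.zph`, the same machinery the source workflow used). The
check is advisory: results are reported, nothing is auto-dropped.

## Stacking

`make_folds()` builds $K$ event-stratified folds whose sizes differ by at
most one, each containing at least one event (re-drawn up to 100 times).
Out-of-fold linear predictors follow standard stacking discipline: a
refittable sub-model is trained $K$ times on $K-1$ folds and evaluated on
the held-out fold; a fixed published signature has no fold dependence and
is evaluated directly. `fit_stacking_weights()` then maximizes the Cox
partial likelihood of the outcome on the out-of-fold columns under the box
constraint $w_m \ge 0$, by L-BFGS-B with the analytic gradient, starting at
$w = 1/M$ with bounds $[0, 10M]$ and projected-gradient tolerance
$10^{-6}$. The meta-fit is deliberately the *linear* Cox fit on the
columns: the published output of this workflow is a single weight per
sub-model, which only the linear form yields directly; smooth per-column
calibration was considered and rejected as the default because it has no
single-weight summary. Weights are normalized to sum to one by default
(the printed weight sets sum to 1.00). At deployment, sub-model linear
predictors come from sub-models refit on the full training data
(`full_linear_predictors()`); out-of-fold values exist only to fit the
weights.

## Final model

Learners run behind a uniform adapter (fit / linear risk / survival
function): random survival forest via `ranger`, XGBoost with the Cox
objective via `xgboost` (survival functions through a Breslow baseline on
the training linear predictor), a linear Cox baseline on the in-package
engine, and a constant-prediction dummy baseline for diagnostics. Adapters
for survival-SVM and classical GBM are declared in the registry and refuse
to train, naming the missing backend. FAB is one-hot encoded over its
declared levels with the largest observed category as reference; age enters
in years, untransformed. `train_learner()` grid-searches by 10-fold
cross-validated Harrell's concordance and refits the winner;
`select_learner()` scores each tuned learner by pooled out-of-fold
time-dependent AUC averaged over the evaluation horizons (365/730/1095
days by default — years are converted as $365k$ days) and breaks ties
toward the simpler learner in registry order. `bootstrap_validate()`
resamples with replacement, refits, and evaluates on the out-of-bag
samples: out-of-bag evaluation is a deliberate choice over resubstitution
(which would be optimistic); replicates with unusable out-of-bag sets are
skipped and counted. All of it is bit-for-bit reproducible under a seed.

## Evaluation

`td_roc()` implements cumulative/dynamic time-dependent ROC: cases have
events by $t$, controls survive beyond $t$. Censoring is handled through a
conditional Kaplan–Meier estimate of $S(t \mid \text{marker})$; the default
is the nearest-neighbour estimator with span $0.25\,n^{-0.20}$ on the
marker-quantile scale, and a subset-KM variant sits behind
`method = "km"` since the upstream tooling offers both and does not say
which produced the published curves. On uncensored data the subset-KM
variant reduces *exactly* to the Mann–Whitney U statistic — the test suite
holds it to $10^{-9}$ — while the smoothed NNE only approaches it.
`optimal_cutpoint()` scans every admissible midpoint (both groups at least
`minprop` = 0.1 of the sample) for the maximal standardized two-group
log-rank statistic; the p-value it reports is the naive one at the selected
cut, with an always-on warning that selection bias is uncorrected — exactly
the workflow being reproduced, not a recommendation. Calibration pairs
binned (or population-mean) predicted survival with Kaplan–Meier estimates
at the horizon; population mode is the default for opaque machine-learning
models. `bonferroni_adjust()` uses the threshold form $\alpha/m$
($0.05/3 = 0.0167$, displayed as 0.017).

## Regrouping

`merge_eln_model()` maps (ELN2017, model risk) to three refined groups.
The source description is internally inconsistent: it assigns ELN
Favorable to the low-risk group yet counts three "remaining" high-risk
subgroups, which is only arithmetically possible if (Favorable, high) is
high. The package defaults to that "remaining three subgroups" reading and
offers the alternative ((Favorable, high) → low) behind
`favorable_high_low = TRUE`.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, with defaults chosen once to match the target cohort conditions:
553 samples; per-gene log2 means in 5–12 and SDs 0.3–1.5; a 10-gene seed
panel named after the canonical cuproptosis genes; a correlated block built
from one latent Gaussian factor per seed gene with Pearson loadings
0.52–0.82 (population Spearman roughly 0.5–0.8, so screen-passing genes
exist by construction); survival times from an exponential-baseline Cox
model ($h_0 = \log 2 / 353$ per day, putting median survival near 353 days
for an average-risk patient); target censoring 0.266; age
$\mathcal{N}(54.9, 14.8^2)$ truncated to [18, 90]; FAB as an 8-level
multinomial with the observed cohort proportions; ELN2017 probabilities
tilted with age (older patients enriched in Adverse) so the clinical
columns are mutually informative — without that, no conditional imputation
method could demonstrably beat marginal imputation; and 3% MCAR
missingness. Censoring is independent exponential with its rate solved in
closed form by `uniroot` from
$\Pr(C < T_i) = r/(r + h_i)$ so the realized censoring fraction tracks the
target. Two numerical notes: survival times are generated from the
mean-centred linear predictor, with the centring constant absorbed into the
baseline (a Cox-invariant shift that keeps `baseline_hazard` in control of
the time scale), while `true_lp` in the ground truth remains the exact
uncentred inner product plus clinical effects; and missingness is MCAR
only, which is what the round-robin random-forest imputer is validated
against here. The generator does **not** emulate probe-level microarray
artifacts, batch structure beyond location/scale shifts, or informative
censoring — so a green test suite says the methods are correct under a
well-specified Cox world with clean censoring, not that they are robust to
those real-data pathologies.

`simulate_submodel_signatures()` grades sub-model informativeness in
$[0,1]$: 1 reproduces the causal signature exactly, 0 draws a disjoint
random gene set with random coefficients, and intermediate values mix the
two — standing in for the external published signatures whose gene lists
are not available.

## Preprocessing

Cross-dataset harmonization restricts to the shared gene set
(intersection, never union — no values are fabricated) and applies full
quantile normalization via `limma::normalizeBetweenArrays`; the upstream
workflow names the function but not the method, and quantile is the
strongest of its options, so the choice is documented rather than silent.
Clinical imputation is missForest-style round-robin random-forest
regression/classification per column (initialized at mean/mode, least
missing column first, stopping when the imputed values change by less than
$10^{-3}$ or after 10 passes), deterministic under a seed, and never
touches observed cells.

## Problem sizes used by the tests

The packaged test-suite exercises the statistical claims at sizes chosen as
the package's own reduced study conditions: spike-and-slab recovery with 3
causal genes ($|\beta| = 0.8$) among 50 candidates at $n = 400$ over 20
replicates with a 6-point $s_0$ grid and 4-fold single-replicate CVPL;
stacking weight recovery at $n = 500$ over 20 replicates; type-I error
calibration of the PH and log-rank tests over 200 null replicates; oracle
equivalences (brute-force cut-point scan, simplex grid for the stacking
weights, Mann–Whitney reduction, exhaustive stepwise enumeration,
fixed-penalty lasso degeneracy, hand-computed product-limit) at small $n$
where the oracles are exact. Bootstrap examples run at reduced $B$; the
production default remains $B = 1000$.

## Known limitations

* The spike-and-slab selection at the CVPL optimum is permissive by design;
  interpretation should rest on the post-stepwise signature.
* Survival-SVM and GBM backends are declared but not bundled.
* The cut-point p-value carries selection bias (warned, uncorrected).
* ELN2017 labels are consumed as input; the genetic classification itself
  is out of scope, as is ELN2022.
* External cohort results (published AUCs, the 0.08 cut-off, the specific
  14-gene refit) require the original datasets and are not reproduced;
  the packaged signature file carries the published coefficients as data.
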