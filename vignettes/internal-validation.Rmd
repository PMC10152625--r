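---
title: "Optimism correction for logistic prediction models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimism correction for logistic prediction models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optivalid)
```

## The problem

A logistic regression model fitted to a small development sample looks
better on its own training data than it will in the population: the
*apparent* c-statistic, discrimination slope, or Brier score is
optimistically biased.  Resampling techniques — cross-validation and the
bootstrap — are the standard internal-validation tools for correcting this
optimism.  They are not interchangeable, however, and their behaviour
interacts with the *estimator* used to fit the model.  Pooled leave-one-out
(LOO) cross-validation in particular is known to bias the c-statistic
downwards, and the bias is amplified for estimators that shrink predicted
probabilities towards the observed event fraction, such as ridge
regression.  `optivalid` implements the estimators, measures, correction
techniques, and a simulation framework for studying these interactions.

## Measures

For predicted probabilities $p_i$ and outcomes $y_i \in \{0,1\}$:

* **c-statistic** — the proportion of event/non-event pairs in which the
  event has the larger prediction; ties count $1/2$, which makes the value
  equal to the area under the ROC curve.  Ties are rare with continuous
  covariates; a `ties = "strict"` mode is available for sensitivity checks.
* **discrimination slope** — $\bar p_{y=1} - \bar p_{y=0}$, equivalently
  the average pairwise difference over contrary-outcome pairs.
* **Brier score** — $n^{-1}\sum_i (y_i - p_i)^2$; defined per observation,
  which is what lets LOO estimate it by averaging.

For any estimator whose mean fitted probability equals the event fraction
(maximum likelihood with an intercept, in particular), the discrimination
slope obeys an exact sum-of-squares decomposition
$$\mathrm{DS} = \tfrac12\left(1 - \mathrm{SSE}/\mathrm{SST}\right) +
  \tfrac12\,\mathrm{SSM}/\mathrm{SST},$$
with SSE the residual and SSM the model sum of squares: the slope is the
average of the residual-based and model-based $R^2$ measures.  The suite
verifies this identity to machine precision; note that the slope does *not*
equal $1-\mathrm{SSE}/\mathrm{SST}$ alone (the discrepancy is visible at
$n=50$ already), which is why the package asserts the two-term form.

## Estimators

* **ML** (`fit_ml`) — Newton/IRLS on the binomial likelihood.  Under
  complete or quasi-separation the maximum-likelihood estimate does not
  exist; the fit is reported at the iteration cap, flagged
  `converged = FALSE`, with the separation status attached.
* **Firth** (`fit_firth`) — maximizes $\ell(\beta) + \frac12\log\det
  I(\beta)$ via modified score equations with hat-diagonal corrections.
  Coefficients stay finite under separation.
* **Ridge** (`fit_ridge`, `tune_ridge`) — maximizes $\ell(\beta) -
  \lambda\lVert\beta_{\text{slopes}}\rVert^2$ with the intercept
  unpenalized and slopes penalized on the standardized scale (each slope
  multiplied by its covariate's standard deviation inside the penalty), so
  the penalty is invariant to the units of measurement; coefficients are
  returned on the original scale.  The tuning parameter is selected by
  minimizing the penalized AIC $-2\ell(\hat\beta) + 2\,df_e$ with
  $$df_e = \operatorname{trace}\!\left[\frac{\partial^2\ell}{\partial\beta^2}
  \left(\frac{\partial^2\ell^{*}}{\partial\beta^2}\right)^{-1}\right],$$
  the effective degrees of freedom ($\ell^{*}$ the penalized
  log-likelihood).  $df_e$ equals the parameter count at $\lambda=0$ and
  decreases towards 1 (the free intercept) as $\lambda\to\infty$.

**Tuning grid.** 96 log-equidistant values spanning $10^{-4}$ to $10^{4}$,
preceded by $\lambda = 0$, fitted with warm starts from the strongest
penalty downwards.  Ties in the criterion break towards the larger
$\lambda$ (more shrinkage at equal fit).  Including 0 matters under
separation, where the penalized AIC may legitimately select no shrinkage
and ridge then inherits the ML divergence — a behaviour of the tuning rule
itself, not an artefact.

**Convergence.** ML and ridge use exact-Hessian Newton steps with
step-halving (quadratic convergence; 25 iterations, coefficient-change
tolerance $10^{-8}$).  The Firth fit is Fisher scoring on the penalized
likelihood — the Hessian omits the derivative of the $\log\det$ term — so
its convergence is linear near the optimum and small datasets regularly
need more than 25 iterations to reach $10^{-8}$ (a few hundred on
nearly flat likelihoods); its iteration cap is therefore 500.  The fitting cores are compiled
(RcppArmadillo) because the resampling techniques refit them thousands of
times per dataset.

## Separation

Complete separation (a linear combination of covariates strictly separates
events from non-events) and quasi-separation (separation with ties on the
boundary) are decided exactly by two small linear programs over the
coefficient box $[-1,1]^{p+1}$: one maximizing the minimal margin
(positive optimum $\Leftrightarrow$ complete separation), one maximizing
the margin sum subject to nonnegative margins (positive optimum
$\Leftrightarrow$ some separation).  A dense primal simplex with Bland's
rule solves them; covariates are rescaled by their maximal absolute value
first so the LP tolerance ($10^{-7}$) is unit-scale.  Because an interior,
converged ML fit certifies overlap, the fitters only invoke the LP when a
fit diverges or probabilities hit the boundary.

## Correction techniques

All techniques replay the full model-development process — including the
ridge tuning search — inside every resample.

* **apparent** — the model evaluated on its own training data.
* **loo** — $n$ refits, each excluding one observation; c-statistic and
  discrimination slope computed once from the *pooled* vector of held-out
  predictions (they are pairwise measures); the Brier score averaged per
  observation, which is identical to pooling.
* **lpo** — every event/non-event pair held out in turn, $k(n-k)$ refits;
  concordance judged within each held-out pair.  The Brier score is not
  offered: averaging it over pairs would weight the two outcome classes
  equally regardless of the event fraction; requesting it is an error.
* **kfold** — `f = 5` folds, `r = 40` repetitions, unstratified random
  partitions with fold sizes differing by at most one; fold-level values
  averaged within a repetition first, then across repetitions (the two
  orders coincide unless folds are dropped).
* **enhanced_boot** — `B = 200` resamples; optimism = mean of
  (measure on the resample − measure on the original data), subtracted
  from the apparent value.
* **boot632plus** — weighted average of the apparent and mean out-of-bag
  value on the error scale ($1-c$ for the c-statistic, $-\mathrm{DS}$, the
  Brier score itself), with weight $w = 0.632/(1-0.368\,\hat R)$ and
  relative overfitting rate $\hat R = (\overline{err}_{oob} -
  err_{app})/(\gamma - err_{app})$ clamped to $[0,1]$,
  $\overline{err}_{oob}$ truncated at the no-information error $\gamma$.
  $\gamma$ is $0.5$ for the c-statistic, the permutation expectation for
  the Brier score ($n^{-2}\sum_i\sum_j (y_i - p_j)^2$), and exactly 0 for
  the discrimination slope (its permutation expectation vanishes for any
  prediction distribution).  The truncation yields the floor property:
  the .632+ c-statistic never falls below $\min(\text{apparent}, 0.5)$.

**Degenerate resamples.**  A bootstrap resample or fold partition whose
training part has a single outcome class or linearly dependent covariate
columns is redrawn up to 50 times, then skipped and counted in
`n_failed`; LOO/LPO subsets cannot be redrawn and are skipped directly.
*Separated* resamples are never redrawn: each estimator's own behaviour
under separation is part of what is being compared.  Fold-level pairwise
measures undefined on a single-class test fold drop that fold from the
repetition average.  All skips are logged in the `notes` attribute.

## Synthetic data-generating mechanism

Covariates mimic the mix of types found in clinical data: a latent
5-dimensional normal draw $Z$ with a fixed, modest correlation matrix
(entries 0–0.3) is transformed into

| column | transform | type |
|---|---|---|
| `x1` | $1\{Z_1 > \Phi^{-1}(0.7)\}$ | binary, prevalence 0.3 |
| `x2` | $\mathrm{trunc}(2 + Z_2)$ | ordinal, levels mostly 0–4 |
| `x3` | $Z_3$ | continuous |
| `x4` | $e^{Z_4}$ | continuous, right-skewed |
| `x5` | $Z_5$ | continuous |

Outcomes are Bernoulli draws from a logistic model.  The 12-scenario grid
crosses $n \in \{50, 100\}$, marginal event fraction $\in \{0.25, 0.5\}$,
and effect size (null/weak/strong).  Intercepts are calibrated by
Monte-Carlo root finding on a $10^6$-row draw to a $10^{-4}$ tolerance on
the event fraction (closed form $\mathrm{logit}(\mathrm{EF})$ for null
scenarios).  The effect-size vectors were calibrated once, on a large
draw, so that the true-model c-statistic is about 0.60 (weak) and 0.68
(strong) — the range actually spanned by the study's validated models —
and then frozen:
`beta_weak = (0.286, 0.131, 0.131, 0.061, 0.131)`,
`beta_strong = (0.561, 0.258, 0.258, 0.119, 0.258)`.
All thresholds, correlations and effect vectors sit in one configuration
block (`dgm_params()`) so they can be swapped wholesale.

**What the generator does and does not emulate.**  It reproduces the
variable-type mix, a realistic dependence structure, controlled marginal
event fractions, and discrimination levels spanning null to moderate.  It
does not reproduce any particular clinical covariate distribution, and at
the default effect sizes separated datasets are much rarer than under
data-generating mechanisms with stronger or more categorical effects; the
separation *machinery* is therefore exercised in tests with amplified
effect vectors.  Passing tests show that the
technique–estimator interactions hold under this mechanism, not that the
package's numbers transfer to any specific clinical dataset.

**Randomness.** Every generator is a pure function of its seed; replicate
and resample substreams are derived deterministically from one master seed
(a mixed linear-congruential derivation kept below $2^{31}$), so a whole
study is reproducible from a single integer and development and validation
draws never share a stream.

## The simulation study

`run_study()` executes scenarios × estimators × techniques × measures.
Per scenario one validation set of 100,000 observations is drawn and
reused across replicates (the scenario's gold standard); each replicate
draws a development set, fits the three estimators, computes all
applicable technique × measure estimates and their independently
validated counterparts, and records the development set's separation
status.  `summarize_replicates()` reports, per cell, the mean difference
(bias), the root mean squared difference
$\mathrm{RMSD} = \sqrt{m^{-1}\sum d_i^2}$, and Monte-Carlo standard
errors: $\mathrm{sd}(d^2)/\sqrt m$ for the mean squared difference and,
by the delta method, that value divided by $2\,\mathrm{RMSD}$ for the
RMSD itself (cross-checked in the suite against a
bootstrap-over-replicates oracle).

The defaults reproduce the full study design (1000 replicates per
scenario, `f = 5`, `r = 40`, `B = 200`, validation size $10^5$) — a
cluster-scale computation dominated by leave-pair-out with the retuned
ridge.  The test suite and the acceptance script run the same machinery at
desk scale: 200 replicates of the most adverse scenario ($n=50$, event
fraction 0.25, null effects), where the headline phenomena are sharpest;
at these sizes the Monte-Carlo standard error of a mean c-statistic
difference is about 0.01.

## Design choices that were genuinely open

* **Tie handling in the c-statistic**: ties count 1/2 (the AUC
  convention); a strict mode exists because the definition via "higher
  probability" is silent about ties.
* **Averaging order in repeated k-fold**: within repetition first; the
  alternative (pooling all $r \cdot f$ fold values) differs only when
  folds are dropped.
* **Redraw-versus-skip for degenerate resamples**: redraw preserves the
  nominal resample count and keeps estimators comparable; the full log
  makes the choice auditable, and the skip counts are reported rather
  than hidden.
* **One validation set per scenario**, reused across replicates: its
  sampling noise (standard deviation of order $10^{-3}$ on a c-statistic)
  enters all replicates of a scenario identically and is negligible
  relative to the replicate-to-replicate spread.
* **Winsorization**: `winsorize_c()` floors c-statistics at 0.5.  At null
  scenarios this reduces the RMSD to the validated value (the suite
  checks the direction), at the cost of discarding the information that
  an estimate fell below chance.

## Known limitations

* The exact covariate transformations and effect vectors of the original
  study design are approximated (calibrated to its printed performance
  anchors), so quantities that depend on fine DGM details — the frequency
  of separated datasets most visibly — need not match it.
* The LOO bias magnitude for ridge depends on the tuning-rule details
  (grid range, penalized-AIC criterion); the package fixes one defensible
  rule and reports what it produces.
* Variance estimation for internally validated measures, calibration-slope
  shrinkage, ROC-curve estimation and split-sample validation are out of
  scope.
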