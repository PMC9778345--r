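---
title: "Estimating a Gaussian copula from data missing at random"
author: "gcmiss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a Gaussian copula from data missing at random}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmiss)
```

## The model

`gcmiss` estimates the joint distribution of a numeric table whose cells
are missing at random (MAR): the probability that a cell is missing may
depend on the *observed* cells of its row, but not on the unobserved
ones. The joint law is modelled as a Gaussian copula: by Sklar's theorem
the distribution function factors into marginals $F_1,\dots,F_p$ and a
copula, and we take the copula to be that of a multivariate normal with
correlation matrix $\Sigma$ (unit diagonal). Equivalently, the latent
scores $Z_j = \Phi^{-1}(F_j(X_j))$ are jointly $N(0,\Sigma)$. The model
therefore extends multivariate normality to arbitrary continuous
marginals while keeping Gaussian conditional algebra: given observed
coordinates $S$ with scores $z_S$, the missing coordinates $T$ have
latent law $N(\mu, \Sigma')$ with $\mu = \Sigma_{T,S}\Sigma_{S,S}^{-1}
z_S$ and $\Sigma'$ the Schur complement, and data-scale conditional
samples are obtained by pushing normal draws through
$F_j^{-1}\circ\Phi$ (`sample_conditional()`).

Zeros of the precision matrix $K = \Sigma^{-1}$ encode conditional
independence between pairs of columns given all others. Expert knowledge
of that kind can be imposed on the estimate as structural zeros
(`structure =` in `gcm()`).

## Why the observed-data ecdf is not enough

Under MAR, the empirical distribution of the *observed* values of a
column is a biased estimate of its marginal: if, say, large values of
$X_1$ make $X_2$ more likely to be missing and the columns are
correlated, the observed $X_2$ values are systematically shifted. Any
procedure that freezes the marginals at the observed-data ecdf (the
SCOPE baseline, `marginals = "empirical"`) inherits this bias. The
package's central estimator instead *parametrizes* each unknown marginal
as an equal-weight Gaussian mixture,
$$F_j(x) = \frac1g \sum_{k=1}^g \Phi\!\left(\frac{x-\theta_{jk}}{\sigma_j}\right),
\qquad \theta_{j1}\le\dots\le\theta_{jg},$$
and estimates the means jointly with $\Sigma$, so the dependence
structure can correct the selection effect on each marginal. The
bandwidth $\sigma_j$ is a fixed hyperparameter (not optimized), set by
the rule of thumb $\sigma_j = 1.06\,\hat\sigma_j\,g^{-1/5}$ from the
standard deviation of the observed values; with $g$ of the order of the
sample size the mixture approaches a kernel estimate. Sorting the means
is a pure relabelling (the mixture is exchangeable in its components)
and fixes identifiability.

## The ECM algorithm

`gcm()` maximizes the observed-data likelihood by Expectation
Conditional Maximization:

1. **E-step.** For each row, the conditional second moment of the latent
   score vector is available in closed form from the Schur complement:
   $V_\ell$ has blocks $z_S z_S^\top$, $z_S\mu^\top$ and
   $\Sigma' + \mu\mu^\top$. The sufficient statistic is
   $S = \frac1N\sum_\ell V_\ell$ (`estep_statistic()`; rows sharing a
   missingness pattern share the linear algebra).
2. **$\Sigma$-update.** The maximizer over unit-diagonal matrices is
   approximated by rescaling $S$ to a correlation matrix, $\Sigma
   \leftarrow P S P$ with $P_{jj} = S_{jj}^{-1/2}$ (`sigma_update()`);
   this is scale invariant in $S$. With structural zeros configured the
   update instead maximizes $-\log|\Sigma| - \mathrm{tr}(\Sigma^{-1}S)$
   subject to $K_{jk}=0$ on the constrained pairs, by the
   known-structure iterative conditional-regression algorithm
   (`constrained_sigma_update()`); the free entries of the solution
   match the normalized statistic, and we re-normalize the diagonal so
   the ECM loop always works on the correlation scale.
3. **$\theta$-update.** The marginal means maximize a Monte Carlo
   estimate of the completed-data objective: each incomplete row is
   completed $M$ times by conditional-copula draws under the *current*
   parameters, and
   $\sum_{\ell,m} w\,[-\tfrac12 z_\theta^\top(K_{t+1}-I)z_\theta +
   \sum_j \log f_j^{\theta_j}]$ is maximized over the means with the
   bandwidths fixed. Fully observed rows are weighted once rather than
   duplicated $M$ times (identical and cheaper). The quadratic term
   couples the marginals through $K_{t+1}$: when a precision entry is
   zero the corresponding marginals decouple, which is how dependence
   knowledge also sharpens marginal estimates.

The optimizer is BFGS with the analytic gradient, warm-started at the
current means; a partial inner ascent preserves the ECM monotonicity, so
the iteration caps are deliberately small. Initialization: $\Sigma_0 =
I$; $\theta_0$ places the means at the $(k-\tfrac12)/g$ empirical
quantiles of the observed values and refines them by least squares
between mixture cdf and ecdf (the fitting loss for the initializer is a
design choice of this package; quantile placement alone is already
close, and the refinement is cheap and deterministic).

**Schedule and convergence.** Defaults: 20 stabilization steps at
$M = 20$, then up to 5 refinement steps at $M = 1000$; the fit stops
when $\lVert\Sigma_{t+1}-\Sigma_t\rVert_1 < 10^{-5}$ (checked in the
refinement phase). The marginal change is logged but not part of the
stopping rule. With frozen marginals (`"empirical"` or a list of known
marginals) the E-step is exact, no Monte Carlo is needed, and the
correlation-only EM runs to the same $L_1$ criterion (cap 500
iterations). One honest caveat: because the correlation rescaling is an
*approximate* conditional maximization, the EM monotonicity guarantee
does not transfer to it — the observed-data log likelihood climbs
overall but can dip by small amounts between iterations, and the
fixpoint can differ slightly from the exact unit-diagonal maximizer.
The test suite verifies that an oracle EM with the exact M-step (a
one-parameter maximization in two dimensions) is monotone to machine
precision, which pins the behaviour on the rescaling approximation
rather than on the E-step.

**Randomness.** One master seed; each (iteration, row) pair derives its
own substream deterministically, so row order does not affect results.

## Numerical choices

* cdf values are clipped to $[10^{-12}, 1-10^{-12}]$ before $\Phi^{-1}$
  — a numerics guard against infinite scores, not a statistical choice.
  Inside the $\theta$-objective the clip is $10^{-10}$ and the
  chain-rule term is frozen at the boundary.
* Schur complements are symmetrized and eigenvalue-clipped at
  $10^{-12}$ before sampling (they can lose definiteness at float
  precision).
* Mixture quantiles are found by safeguarded Newton on a bracket that is
  exact for equal-weight mixtures: the quantile lies between
  $\min_k\theta_k + \sigma\Phi^{-1}(u)$ and
  $\max_k\theta_k + \sigma\Phi^{-1}(u)$; tolerance $10^{-15}$ on the cdf
  scale. The hot kernels (mixture cdf/pdf/quantile, objective +
  gradient) are implemented in C++.
* The empirical marginal uses the pseudo-observation convention
  $\tfrac{n}{n+1}\hat F$ floored at $\tfrac1{n+1}$, so its normal scores
  are always finite; below the sample minimum the floor value applies.
* The constrained update cycles until entry changes fall below
  $10^{-8}$, cap 500 cycles, warning (not error) on non-convergence.

## The synthetic-data designs

Two generators reproduce the package's reference study conditions.

* `design_2d()`: $\chi^2_6$ and $\chi^2_7$ marginals coupled at latent
  correlation $\rho$ ($N = 100$, $\rho = 0.5$ by default); every cell is
  thinned MCAR with probability `p_mcar`, then column 2 of
  still-complete rows is masked with the logistic MAR probability
  $1/(1+e^{-\beta_0-\beta_1 z_1})$ driven by the latent score of the
  observed column 1 (default $\beta = (0,2)$, which masks about half of
  column 2 and visibly left-shifts its observed distribution).
  The MCAR layer's level is a free parameter of the design; 0.1 is a
  small thinning chosen once so that both columns can be missing, as
  the design implies, and it is flagged in reports.
* `design_3d()`: $\chi^2$ marginals with 6, 7 and 5 degrees of freedom,
  $N = 50$, and the correlation implied by normalizing the precision
  pattern $[[1,.5,.5],[.5,1,0],[.5,0,1]]$ to unit diagonal, so columns
  2 and 3 are conditionally independent given column 1
  ($\Sigma_{12}=\Sigma_{13}=-1/\sqrt3$, $\Sigma_{23}=1/3$). Columns 1–2
  are thinned MCAR; column 3 is masked, when 1–2 are observed, with
  logistic probability in both latent scores. The coefficients of this
  three-dimensional mechanism are design choices of this package,
  mirroring the two-dimensional mechanism: it fixes $\beta_0=0$,
  $\beta_1=\beta_2=1$, `p_mcar = 0.1` once, exposes them in the design
  object, and all
  mechanism-sensitive magnitudes (Frobenius error level, divergence
  level) should be read with that in mind — orderings between methods
  are the robust comparison.

What the generators do *not* emulate: discrete or heavy-tailed
marginals, missingness not at random, monotone longitudinal patterns,
and model misspecification of the copula itself. Passing tests on these
designs show correct recovery *within* the Gaussian-copula/MAR world,
not robustness outside it.

## Evaluation tools

`cramer_von_mises()` computes $c\int(\hat F - F)^2\,dF$ by a
2,000-point quadrature in $u = F(x)$. The constant $c$ is purely a
reporting convention (default 1000, matching the magnitudes customary in
simulation tables); comparisons between methods do not depend on it, and
the package never treats $\omega$ magnitudes as reference-comparable.
`kl_divergence()` estimates the divergence from the true to the fitted
model by Monte Carlo with its standard error; it requires densities, so
it is undefined for fits with empirical marginals. `replicate_study()`
runs any subset of the estimators over independently generated datasets
and keeps the full per-replicate vectors, so summary tables are always
recomputable.

## Known limitations

* The frozen-ecdf (SCOPE) baseline is *inconsistent* under
  selection-driven MAR, and more so than its literature reputation
  suggests: its rank-based scores are marginally standard by
  construction, which erases the variance compression of the selected
  sample that the Gaussian E-step needs in order to undo the selection.
  Under the default two-dimensional design its mean correlation
  estimate attenuates to about 0.33 (truth 0.5; the acceptance script
  recomputes this) while the known-marginals fit is nearly unbiased;
  under MCAR both are unbiased. The package reports what the
  estimator actually does.
* The mixture update maximizes a Monte Carlo objective; with the default
  schedule the residual Monte Carlo noise in $\hat\Sigma$ is of order
  $10^{-3}$ — negligible against sampling error at the study sizes, but
  the fit is only reproducible under a fixed seed.
* Standard errors for the fitted parameters are out of scope
  (bootstrapping is possible in principle); soft or penalized
  dependence constraints are an extension point, not implemented.
* Replication scales used by the test suite: 1000 replicates for the
  correlation-only baselines, 100 for the mixture fits and the
  three-dimensional study, 300 at $N = 1000$. These were chosen as the
  package's own compromise between Monte Carlo error and turnaround.

## A worked example

```{r example, eval = FALSE}
d <- design_2d(N = 200)
sim <- simulate_design(d, seed = 7)
fit <- gcm(sim$data, marginals = "mixture", seed = 7)
summary(fit)
coef(fit)                      # latent correlation
plot(fit)                      # fitted vs observed-data marginal cdfs
imp <- predict(fit)            # conditional-expectation imputation
cramer_von_mises(fit$model$marginals[[2]], d$model$marginals[[2]])
```
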