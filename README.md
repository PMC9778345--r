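# gcmiss — Gaussian copula estimation with missing data

`gcmiss` estimates the joint distribution of a multivariate numeric
dataset whose cells are **missing at random** (MAR): missingness may
depend on the observed values of a row, but not on the unobserved ones.
It is aimed at statisticians and applied researchers (epidemiology,
manufacturing, social science) who need a full joint model — for
imputation, conditional prediction, or downstream decision making —
rather than column-by-column summaries.

## The model and the algorithm

The joint law is a **Gaussian copula**: marginals `F_1, …, F_p` plus a
correlation matrix `Σ` coupling the latent normal scores
`Z_j = Φ⁻¹(F_j(X_j)) ~ N(0, Σ)`. Under MAR the empirical distribution of
a column's *observed* values is biased — selection through correlated
columns shifts it — so marginals and dependence must be estimated
*together*. `gcmiss` does this with an **Expectation Conditional
Maximization (ECM)** algorithm:

* **E-step** — the conditional second moment of each row's latent score
  vector is available in closed form (Schur complement), yielding the
  sufficient statistic `S = (1/N) Σ_ℓ V_ℓ`;
* **Σ-update** — `S` is rescaled to a correlation matrix
  (`Σ ← P S P`, `P_jj = S_jj^{-1/2}`), or, when conditional
  independencies are known a priori, maximized under **structural zeros
  of the precision matrix** `Σ⁻¹` by the known-structure iterative
  conditional-regression algorithm;
* **θ-update** — each unknown marginal is an equal-weight Gaussian
  mixture `F_j(x) = (1/g) Σ_k Φ((x − θ_jk)/σ_j)` with fixed bandwidth
  `σ_j = 1.06 σ̂_j g^{-1/5}`; the means maximize a Monte Carlo
  completed-data objective built from conditional-copula draws of the
  missing cells.

Baselines with frozen marginals are included: the rescaled
observed-data ecdf (**SCOPE**) and fully known marginals — both reduce
to an exact correlation-only EM. Synthetic-data designs
(`design_2d()`, `design_3d()`), evaluation metrics (Cramér–von Mises,
Frobenius error, Kullback–Leibler divergence) and a replication engine
(`replicate_study()`) reproduce the reference simulation studies.

## A worked example

```r
library(gcmiss)
d   <- design_2d(N = 200)            # chi-sq(6)/chi-sq(7), rho = 0.5, MAR on column 2
sim <- simulate_design(d, seed = 7)  # 31.4% of cells missing
fit <- gcm(sim$data, marginals = "mixture", seed = 7)
fit
#> Gaussian copula fit (em), 199 x 2 data, 125 missing cells (31.4%)
#> 25 iterations, NOT converged (final L1 change 0.00081)
#> Correlation matrix:
#>        X1     X2
#> X1 1.0000 0.5436
#> X2 0.5436 1.0000
coef(fit)
#>    rho_12
#> 0.5435806
```

The fitted latent correlation 0.544 is close to the known-marginals
reference fit on the same data (0.549; truth 0.5 — both carry sampling
error at N = 200), while the frozen-ecdf baseline attenuates to 0.439.
The fit stops here on its step budget with the correlation still moving
at the 8×10⁻⁴ level, well below sampling error. The mixture marginal
also repairs the selection bias of the observed-data ecdf: its
Cramér–von Mises distance to the true second marginal is 0.13 versus
5.76 for the raw ecdf of the observed values. `plot(fit)` overlays the
two cdfs; `predict(fit)` imputes the missing cells from the fitted
conditional distribution; `simulate(fit, n)` draws new complete rows.

Expert knowledge enters as precision zeros — e.g.
`gcm(x, marginals = "mixture", structure = cbind(2, 3))` forces columns
2 and 3 to be conditionally independent given the rest, which improves
both the dependence estimate and the marginals in the
`design_3d()` study.

A command-line front end (`inst/cli/gcmiss.R`) exposes `fit`,
`simulate`, `replicate` and `evaluate` subcommands over CSV files with
empty-cell missing tokens.

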