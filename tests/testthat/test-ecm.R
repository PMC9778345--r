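test_that("complete data with frozen marginals converges to the normalized
           latent correlation in one step and is a fixpoint", {
  set.seed(61)
  model <- gc_model(matrix(c(1, .5, .5, 1), 2),
                    list(chisq_marginal(6), chisq_marginal(7)))
  x <- sample_joint(model, 400)
  fit <- gcm(x, marginals = model$marginals, seed = 1)
  z <- to_latent(x, model$marginals)
  expect_equal(fit$model$sigma, sigma_update(crossprod(z) / 400),
               tolerance = 1e-12)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)   # step two only confirms the fixpoint
})

test_that("correlation-only EM with an exact conditional maximization is
           monotone, and the rescaled update still climbs overall", {
  for (s in c(71, 3009, 3014)) {
    dat <- toy_mar_data(N = 150, rho = 0.6, p_miss = 0.3, seed = s)
    z <- gcmiss:::latent_matrix(dat$x, dat$model$marginals)
    # oracle EM: exact maximization of -log|Sigma| - tr(Sigma^{-1} S)
    # over unit-diagonal 2x2 matrices; EM theory applies exactly here
    rho <- 0; lls <- numeric(60)
    for (t in 1:60) {
      S <- estep_statistic(z, matrix(c(1, rho, rho, 1), 2))
      obj <- function(r) {
        Sig <- matrix(c(1, r, r, 1), 2)
        -determinant(Sig)$modulus - sum(diag(solve(Sig, S)))
      }
      rho <- optimize(obj, c(-0.999, 0.999), maximum = TRUE, tol = 1e-12)$maximum
      lls[t] <- observed_loglik_sigma(z, matrix(c(1, rho, rho, 1), 2))
    }
    expect_true(all(diff(lls) > -1e-10))
    # the correlation-rescaled update is an approximate conditional
    # maximization: per-step monotonicity is not guaranteed, but the
    # fit must end far above its first iterate and near the oracle
    fit <- gcm(dat$x, marginals = dat$model$marginals, seed = 1)
    tr <- fit$trajectory$objective
    expect_gt(tr[length(tr)], tr[1])
    expect_equal(fit$model$sigma[1, 2], rho, tolerance = 0.12)
  }
})

test_that("known-marginals fit recovers the correlation under MCAR", {
  set.seed(81)
  model <- gc_model(matrix(c(1, .5, .5, 1), 2),
                    list(chisq_marginal(6), chisq_marginal(7)))
  x <- sample_joint(model, 5000)
  x[matrix(runif(10000) < 0.2, 5000, 2)] <- NA_real_
  x <- x[rowSums(!is.na(x)) > 0, ]
  fit <- gcm(x, marginals = model$marginals, seed = 2)
  expect_equal(fit$model$sigma[1, 2], 0.5, tolerance = 0.05)
  # consistency: the error shrinks with N (checked against a small run)
  xs <- sample_joint(model, 500)
  xs[matrix(runif(1000) < 0.2, 500, 2)] <- NA_real_
  xs <- xs[rowSums(!is.na(xs)) > 0, ]
  fit_s <- gcm(xs, marginals = model$marginals, seed = 2)
  expect_equal(fit_s$model$sigma[1, 2], 0.5, tolerance = 0.2)
})

test_that("fits are bit-identical under a fixed seed", {
  dat <- toy_mar_data(N = 80, seed = 91)
  f1 <- gcm(dat$x, marginals = "empirical", seed = 7)
  f2 <- gcm(dat$x, marginals = "empirical", seed = 7)
  expect_identical(f1$model$sigma, f2$model$sigma)
  expect_identical(f1$trajectory, f2$trajectory)

  ctrl <- gcm_control(g = 5, M_small = 10, steps_small = 3, M_large = 50,
                      steps_large = 2)
  g1 <- gcm(dat$x, marginals = "mixture", control = ctrl, seed = 7)
  g2 <- gcm(dat$x, marginals = "mixture", control = ctrl, seed = 7)
  expect_identical(g1$model$sigma, g2$model$sigma)
  expect_identical(vapply(g1$model$marginals, function(m) m$means, numeric(5)),
                   vapply(g2$model$marginals, function(m) m$means, numeric(5)))
})

test_that("the empirical-marginal path equals freezing the same marginals", {
  dat <- toy_mar_data(N = 100, seed = 101)
  marg <- lapply(1:2, function(j) empirical_marginal(dat$x[, j]))
  f_scope <- gcm(dat$x, marginals = "empirical", seed = 1)
  f_frozen <- gcm(dat$x, marginals = marg, seed = 1)
  expect_equal(f_scope$model$sigma, f_frozen$model$sigma, tolerance = 1e-12)
})

test_that("mixture ECM keeps a unit-diagonal PSD correlation at every step
           and its Monte Carlo objective does not decrease materially", {
  dat <- toy_mar_data(N = 120, rho = 0.5, p_miss = 0.25, seed = 111)
  fit <- gcm(dat$x, marginals = "mixture", seed = 5)
  expect_silent(check_correlation(fit$model$sigma))
  for (m in fit$model$marginals) expect_true(all(diff(m$means) >= 0))
  # objective across the large-M refinement phase: no decrease beyond
  # 3 combined Monte Carlo standard errors
  tr <- fit$trajectory[fit$trajectory$M >= fit$control$M_large, ]
  if (nrow(tr) >= 2) {
    dif <- diff(tr$objective)
    tol3 <- 3 * sqrt(tr$objective_se[-1]^2 + tr$objective_se[-nrow(tr)]^2)
    expect_true(all(dif > -tol3))
  }
})

test_that("data validation names the offending row or column", {
  x <- matrix(c(NA, 1, 2, NA, 3, 4), 3, 2)
  x[1, ] <- NA
  expect_error(gcm(x), "row 1")
  y <- cbind(c(1, NA, NA, NA), c(1, 2, 3, 4))
  expect_error(gcm(y), "column 1")
  expect_error(gcm(matrix(letters[1:4], 2)), "numeric")
})
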