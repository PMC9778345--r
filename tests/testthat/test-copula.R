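test_that("latent transform and its inverse are mutual inverses", {
  # standard normal marginals: the transform is the identity
  mn <- list(normal_marginal(), normal_marginal())
  x <- c(-1.3, 0.7)
  expect_equal(to_latent(x, mn), x)
  expect_equal(from_latent(x, mn), x)

  # chi-square: the median maps to latent zero and back
  mc <- list(chisq_marginal(6))
  expect_equal(to_latent(qchisq(0.5, 6), mc), 0, tolerance = 1e-10)
  expect_equal(from_latent(0, mc), qchisq(0.5, 6), tolerance = 1e-8)

  set.seed(5)
  marginals <- list(chisq_marginal(6), chisq_marginal(7),
                    mixture_marginal(c(1, 3, 6), 1.2))
  x <- cbind(rchisq(50, 6), rchisq(50, 7), rnorm(50, 3, 2))
  z <- to_latent(x, marginals)
  expect_equal(from_latent(z, marginals), x, tolerance = 1e-8)
})

test_that("joint log density factorizes correctly", {
  marginals <- list(chisq_marginal(6), chisq_marginal(7))
  # independence: density is the product of the marginals
  m_ind <- gc_model(diag(2), marginals)
  x <- cbind(c(3, 8), c(5, 2))
  expect_equal(gc_log_density(x, m_ind),
               log(dchisq(x[, 1], 6)) + log(dchisq(x[, 2], 7)))

  # standard normal marginals: multivariate normal density
  set.seed(6)
  sigma <- random_correlation(3, seed = 6)
  m_norm <- gc_model(sigma, list(normal_marginal(), normal_marginal(),
                                 normal_marginal()))
  z <- matrix(rnorm(300), 100, 3)
  K <- solve(sigma)
  manual <- -0.5 * as.numeric(determinant(sigma)$modulus) -
    0.5 * rowSums((z %*% (K - diag(3))) * z) + rowSums(dnorm(z, log = TRUE))
  expect_equal(gc_log_density(z, m_norm), manual, tolerance = 1e-10)

  # conditional factorization f(x1, x2) = f1(x1) f(x2 | x1)
  rho <- 0.5
  m2 <- gc_model(matrix(c(1, rho, rho, 1), 2), marginals)
  x12 <- c(5, 6)
  lhs <- gc_log_density(x12, m2)
  rhs <- log(dchisq(5, 6)) +
    log(cond_density_2d(6, 5, rho, marginals[[1]], marginals[[2]]))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("joint density integrates to one in two dimensions", {
  m <- gc_model(matrix(c(1, .5, .5, 1), 2),
                list(chisq_marginal(6), chisq_marginal(7)))
  # substitute u_j = F_j(x_j): the integral becomes the copula density
  # integral over the unit square; midpoint rule on a fine grid
  n <- 400
  u <- (seq_len(n) - 0.5) / n
  z <- qnorm(u)
  K <- solve(m$sigma)
  ld <- determinant(m$sigma)$modulus
  total <- 0
  for (i in seq_len(n)) {
    q <- K[1, 1] * z[i]^2 + 2 * K[1, 2] * z[i] * z + K[2, 2] * z^2
    total <- total + sum(exp(-0.5 * as.numeric(ld) -
                               0.5 * (q - z[i]^2 - z^2))) / n^2
  }
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("conditional parameters follow the Schur complement", {
  # independence: conditioning changes nothing
  cp <- conditional_params(c(1, -1), diag(4), c(1, 2), c(3, 4))
  expect_equal(cp$mu, c(0, 0))
  expect_equal(cp$sigma_prime, diag(2))

  # bivariate scalar case
  rho <- 0.7
  cp2 <- conditional_params(1.5, matrix(c(1, rho, rho, 1), 2), 1, 2)
  expect_equal(cp2$mu, rho * 1.5)
  expect_equal(as.numeric(cp2$sigma_prime), 1 - rho^2)

  # three-dimensional design matrix vs a generic linear-solve oracle
  sigma <- build_sigma_3d()
  z1 <- 0.8
  cp3 <- conditional_params(z1, sigma, 1, c(2, 3))
  A <- sigma[2:3, 1, drop = FALSE] %*% solve(sigma[1, 1, drop = FALSE])
  expect_equal(cp3$mu, as.numeric(A * z1))
  expect_equal(cp3$sigma_prime,
               sigma[2:3, 2:3] - A %*% sigma[1, 2:3, drop = FALSE],
               tolerance = 1e-12)

  # empty conditioning set: unconditional law
  cp0 <- conditional_params(numeric(0), sigma, integer(0), 1:3)
  expect_equal(cp0$mu, rep(0, 3))
  expect_equal(cp0$sigma_prime, sigma, tolerance = 1e-9)
  expect_error(conditional_params(1, sigma, 1, c(1, 2)), "overlap")
})

test_that("conditional sampling matches the conditional law", {
  set.seed(77)
  rho <- 0.9
  model <- gc_model(matrix(c(1, rho, rho, 1), 2),
                    list(normal_marginal(), normal_marginal()))
  draws <- sample_conditional(2, model, S = 1, m = 50000)
  expect_equal(mean(draws), rho * 2,
               tolerance = 3 * sqrt(1 - rho^2) / sqrt(50000) / (rho * 2))
  expect_equal(sd(draws), sqrt(1 - rho^2), tolerance = 0.02)
  # empirical cdf of the draws vs the closed-form conditional cdf
  grid <- seq(0.5, 3.1, length.out = 50)
  emp <- vapply(grid, function(g) mean(draws <= g), numeric(1))
  expect_lt(max(abs(emp - pnorm(grid, rho * 2, sqrt(1 - rho^2)))), 0.02)

  # independence: draws follow the unconditional marginal
  m_ind <- gc_model(diag(2), list(chisq_marginal(6), chisq_marginal(7)))
  d2 <- sample_conditional(3, m_ind, S = 1, m = 20000)
  expect_gt(ks.test(d2, pchisq, df = 7)$p.value, 0.01)
})

test_that("joint sampling reproduces marginals and latent correlation", {
  set.seed(8)
  m_ind <- gc_model(diag(2), list(normal_marginal(), normal_marginal()))
  x <- sample_joint(m_ind, 10000)
  expect_lt(max(abs(cov(x) - diag(2))), 0.05)

  rho <- 0.5
  m2 <- gc_model(matrix(c(1, rho, rho, 1), 2),
                 list(chisq_marginal(6), chisq_marginal(7)))
  y <- sample_joint(m2, 10000)
  z <- cbind(qnorm(pchisq(y[, 1], 6)), qnorm(pchisq(y[, 2], 7)))
  expect_equal(cor(z)[1, 2], rho, tolerance = 0.03)

  set.seed(123); a <- sample_joint(m2, 5)
  set.seed(123); b <- sample_joint(m2, 5)
  expect_identical(a, b)
})

test_that("precision zeros identify conditional independencies", {
  expect_true(precision_zero(diag(3), 1, 2))
  sigma <- build_sigma_3d()
  expect_true(precision_zero(sigma, 2, 3))
  expect_false(precision_zero(sigma, 1, 2))
  expect_false(precision_zero(sigma, 1, 3))
  expect_false(precision_zero(matrix(c(1, .4, .4, 1), 2), 1, 2))
})

test_that("correlation validation rejects malformed matrices", {
  expect_error(check_correlation(matrix(c(1, .5, .4, 1), 2)), "symmetric")
  expect_error(check_correlation(matrix(c(2, 0, 0, 2), 2)), "unit diagonal")
  expect_error(check_correlation(matrix(c(1, 1, 1, 1), 2)), "positive definite")
  expect_silent(check_correlation(build_sigma_3d()))
})
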