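test_that("per-row statistic has the conditional second-moment block form", {
  marginals <- list(normal_marginal(), normal_marginal())
  # independence: block-diagonal with identity on the missing block
  V <- row_statistic(c(1.2, NA), marginals, diag(2))
  expect_equal(V, diag(c(1.2^2, 1)))

  # fully observed row: rank-one outer product
  sigma <- matrix(c(1, .6, .6, 1), 2)
  V2 <- row_statistic(c(0.5, -1), marginals, sigma)
  expect_equal(V2, tcrossprod(c(0.5, -1)))
  expect_equal(qr(V2)$rank, 1L)

  # scalar conditional moments: z1 = 1, x2 missing, rho = 0.8
  rho <- 0.8
  V3 <- row_statistic(c(1, NA), marginals, matrix(c(1, rho, rho, 1), 2))
  expect_equal(V3, matrix(c(1, rho, rho, (1 - rho^2) + rho^2), 2))
})

test_that("pattern-grouped aggregation equals the row-wise average", {
  set.seed(31)
  p <- 3
  sigma <- random_correlation(p, seed = 31)
  marginals <- list(chisq_marginal(6), chisq_marginal(7), chisq_marginal(5))
  model <- gc_model(sigma, marginals)
  x <- sample_joint(model, 40)
  mask <- matrix(runif(40 * p) < 0.3, 40, p)
  mask[rowSums(mask) == p, 1] <- FALSE
  x[mask] <- NA_real_
  z <- gcmiss:::latent_matrix(x, marginals)
  S_fast <- estep_statistic(z, sigma)
  S_slow <- Reduce(`+`, lapply(seq_len(40), function(l)
    row_statistic(x[l, ], marginals, sigma))) / 40
  expect_equal(S_fast, (S_slow + t(S_slow)) / 2, tolerance = 1e-10)
  expect_true(min(eigen(S_fast, symmetric = TRUE)$values) > -1e-10)
})

test_that("correlation update rescales the statistic and is scale invariant", {
  expect_equal(sigma_update(diag(3)), diag(3))
  expect_equal(sigma_update(matrix(c(4, 1, 1, 1), 2)),
               matrix(c(1, .5, .5, 1), 2))
  set.seed(13)
  S <- crossprod(matrix(rnorm(40), 10, 4)) / 10
  expect_equal(sigma_update(3.7 * S), sigma_update(S))
  expect_equal(diag(sigma_update(S)), rep(1, 4))
  expect_error(sigma_update(matrix(c(0, 0, 0, 1), 2)), "degenerate")
})

test_that("observed-data log likelihood sums the observed Gaussian blocks", {
  z <- rbind(c(0.5, -1), c(NA, 2), c(1, NA))
  ll_id <- observed_loglik_sigma(z, diag(2))
  expect_equal(ll_id, sum(dnorm(c(0.5, -1, 2, 1), log = TRUE)))
  sigma <- matrix(c(1, .6, .6, 1), 2)
  zc <- matrix(rnorm(20), 10, 2)
  manual <- sum(apply(zc, 1, function(r)
    -log(2 * pi) - 0.5 * log(det(sigma)) -
      0.5 * drop(r %*% solve(sigma) %*% r)))
  expect_equal(observed_loglik_sigma(zc, sigma), manual, tolerance = 1e-10)
})

test_that("completions repeat observed cells and track the conditional mean", {
  dat <- toy_mar_data(N = 60, rho = 0.9, p_miss = 0.25, seed = 9)
  model <- dat$model
  comps <- gcmiss:::draw_completions(dat$x, model, M = 400, seed = 3, iter = 1)
  expect_equal(sum(comps$w), nrow(dat$x))
  # observed coordinates are verbatim copies
  for (l in unique(comps$row)) {
    rows <- comps$x[comps$row == l, , drop = FALSE]
    for (j in which(!is.na(dat$x[l, ])))
      expect_true(all(rows[, j] == dat$x[l, j]))
  }
  # with rho = 0.9 the latent completion means track rho * z_obs
  mis2 <- which(is.na(dat$x[, 2]) & !is.na(dat$x[, 1]))
  l <- mis2[1]
  z1 <- to_latent(dat$x[l, 1], model$marginals[1])
  zdraws <- to_latent(comps$x[comps$row == l, 2], model$marginals[2])
  expect_equal(mean(zdraws), 0.9 * z1,
               tolerance = 4 * sqrt(1 - 0.81) / sqrt(400) + 1e-6)

  # complete data: completions are the data itself
  cc <- gcmiss:::draw_completions(dat$model |> sample_joint(10), model,
                                  M = 50, seed = 1, iter = 1)
  expect_equal(nrow(cc$x), 10L)
  expect_equal(cc$w, rep(1, 10))
})

test_that("theta objective reduces, separates and ascends as the theory says", {
  set.seed(41)
  g <- 4
  x <- cbind(rnorm(300, 2, 1.5), rnorm(300, -1, 2))
  comps <- list(x = x, w = rep(1, 300), row = seq_len(300))
  sigmas <- c(0.8, 1.1)
  th <- rbind(c(0, -3), c(1, -1), c(2, 0), c(4, 2))
  marg <- list(mixture_marginal(th[, 1], sigmas[1]),
               mixture_marginal(th[, 2], sigmas[2]))

  # K = I: pure marginal fit, the quadratic term vanishes
  obj_id <- theta_objective(th, sigmas, comps, diag(2))
  manual <- sum(log(marginal_density(marg[[1]], x[, 1]))) +
    sum(log(marginal_density(marg[[2]], x[, 2])))
  expect_equal(obj_id, manual, tolerance = 1e-8)

  # block-diagonal precision: cross second derivatives vanish
  K <- diag(2)
  f <- function(a, b) {
    th2 <- th; th2[1, 1] <- a; th2[1, 2] <- b
    theta_objective(th2, sigmas, comps, K)
  }
  h <- 1e-4
  cross <- (f(h, h) - f(h, -h) - f(-h, h) + f(-h, -h)) / (4 * h^2)
  expect_lt(abs(cross), 1e-4)
  # with a dependent precision the cross derivative is nonzero
  Kd <- solve(matrix(c(1, .8, .8, 1), 2))
  fd <- function(a, b) {
    th2 <- th; th2[1, 1] <- a; th2[1, 2] <- b
    theta_objective(th2, sigmas, comps, Kd)
  }
  crossd <- (fd(h, h) - fd(h, -h) - fd(-h, h) + fd(-h, -h)) / (4 * h^2)
  expect_gt(abs(crossd), 1e-2)

  # one conditional maximization does not decrease the objective
  obj_kd <- theta_objective(th, sigmas, comps, Kd)
  up <- gcmiss:::theta_update(marg, comps, Kd, maxit = 20)
  thup <- vapply(up$marginals, function(m) m$means, numeric(g))
  expect_gte(theta_objective(thup, sigmas, comps, Kd), obj_kd - 1e-8)
  for (m in up$marginals) expect_true(all(diff(m$means) >= 0))
})

test_that("mixture means are recovered from complete data at K = I", {
  set.seed(51)
  true_means <- c(-3, 0, 3)
  sig <- 1
  x <- matrix(rnorm(2000, sample(true_means, 2000, replace = TRUE), sig), ncol = 1)
  comps <- list(x = x, w = rep(1, 2000), row = seq_len(2000))
  start <- list(mixture_marginal(true_means + rnorm(3, 0, 0.3), sig))
  up <- gcmiss:::theta_update(start, comps, matrix(1, 1, 1), maxit = 100)
  expect_equal(up$marginals[[1]]$means, true_means, tolerance = 0.15)
})
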