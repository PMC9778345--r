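# Shared oracles and fixture builders for the test suite. Everything is
# generated in code; oracles are kept independent of the implementation
# paths they check.

# central finite difference
num_deriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# brute-force maximizer of the precision-constrained Gaussian likelihood
# log|K| - tr(K S) over the free entries of K (constrained entries fixed
# at zero); returns the implied covariance K^{-1}
bruteforce_constrained_sigma <- function(S, pairs) {
  p <- nrow(S)
  fixed <- matrix(FALSE, p, p)
  fixed[pairs] <- TRUE
  fixed[pairs[, 2:1, drop = FALSE]] <- TRUE
  ut <- which(upper.tri(S, diag = TRUE) & !fixed, arr.ind = TRUE)
  build_K <- function(par) {
    K <- matrix(0, p, p)
    for (i in seq_len(nrow(ut))) {
      K[ut[i, 1], ut[i, 2]] <- par[i]
      K[ut[i, 2], ut[i, 1]] <- par[i]
    }
    K
  }
  nll <- function(par) {
    K <- build_K(par)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(1e10)
    -(sum(log(ev)) - sum(K * S))
  }
  start <- solve(S)[cbind(ut[, 1], ut[, 2])]
  fit <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  fit <- optim(fit$par, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  solve(build_K(fit$par))
}

# closed-form KL divergence between zero-mean Gaussians N(0, S1) -> N(0, S2)
gaussian_kl <- function(S1, S2) {
  p <- nrow(S1)
  0.5 * (determinant(S2)$modulus - determinant(S1)$modulus +
           sum(diag(solve(S2, S1))) - p)
}

# conditional density oracle for a 2-d Gaussian copula: f(x2 | x1)
cond_density_2d <- function(x2, x1, rho, m1, m2) {
  z1 <- qnorm(marginal_cdf(m1, x1))
  z2 <- qnorm(marginal_cdf(m2, x2))
  mu <- rho * z1
  s2 <- 1 - rho^2
  dnorm(z2, mu, sqrt(s2)) / dnorm(z2) * marginal_density(m2, x2)
}

# random correlation matrix with unit diagonal
random_correlation <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + p * diag(p)
  D <- diag(1 / sqrt(diag(S)))
  D %*% S %*% D
}

# small 2-d dataset with MCAR holes, chi-square marginals, latent rho
toy_mar_data <- function(N = 120, rho = 0.5, p_miss = 0.2, seed = 42) {
  set.seed(seed)
  model <- gc_model(matrix(c(1, rho, rho, 1), 2),
                    list(chisq_marginal(6), chisq_marginal(7)))
  x <- sample_joint(model, N)
  mask <- matrix(runif(2 * N) < p_miss, N, 2)
  mask[rowSums(mask) == 2, 2] <- FALSE   # keep every row partly observed
  x[mask] <- NA_real_
  list(x = x, model = model)
}
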