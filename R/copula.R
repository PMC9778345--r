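#' Validate a correlation matrix
#'
#' Checks symmetry, unit diagonal and positive definiteness.
#' @param sigma numeric matrix.
#' @param tol symmetry/diagonal tolerance.
#' @return `sigma`, invisibly, after validation.
#' @export
check_correlation <- function(sigma, tol = 1e-8) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma))
    stop("'sigma' must be a square matrix")
  if (max(abs(sigma - t(sigma))) > tol) stop("'sigma' is not symmetric")
  if (max(abs(diag(sigma) - 1)) > tol) stop("'sigma' must have unit diagonal")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'sigma' is not positive definite")
  invisible(sigma)
}

# Symmetrize and clip eigenvalues at `floor`; guards Schur complements that
# lose positive semi-definiteness at float precision.
psd_repair <- function(a, floor = 1e-12) {
  a <- (a + t(a)) / 2
  e <- eigen(a, symmetric = TRUE)
  if (min(e$values) < floor) {
    a <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
    a <- (a + t(a)) / 2
  }
  a
}

# cdf values are clipped to this band before qnorm so latent scores stay
# finite; a numerics guard, not a statistical choice
.CDF_EPS <- 1e-12

#' Latent Gaussian transform of a Gaussian copula
#'
#' `to_latent` maps data-scale values to latent normal scores
#' `z_j = qnorm(F_j(x_j))`; `from_latent` applies the inverse map
#' `x_j = F_j^{-1}(pnorm(z_j))`. Both accept a vector (one observation,
#' possibly a subset of columns) or a matrix (rows = observations).
#'
#' @param x numeric vector or matrix of data-scale values.
#' @param marginals list of marginal objects, one per column of `x`.
#' @return numeric vector/matrix of the same shape.
#' @export
to_latent <- function(x, marginals) {
  if (is.matrix(x)) {
    z <- x
    for (j in seq_along(marginals))
      z[, j] <- to_latent(x[, j], marginals[j])
    return(z)
  }
  if (length(marginals) == 1L && length(x) > 1L) {
    u <- marginal_cdf(marginals[[1L]], x)
    return(qnorm(pmin(pmax(u, .CDF_EPS), 1 - .CDF_EPS)))
  }
  if (length(x) != length(marginals))
    stop("length of 'x' must match the number of marginals")
  u <- vapply(seq_along(x), function(j) marginal_cdf(marginals[[j]], x[j]),
              numeric(1))
  qnorm(pmin(pmax(u, .CDF_EPS), 1 - .CDF_EPS))
}

#' @rdname to_latent
#' @param z numeric vector or matrix of latent normal scores.
#' @export
from_latent <- function(z, marginals) {
  if (is.matrix(z)) {
    x <- z
    for (j in seq_along(marginals))
      x[, j] <- from_latent(z[, j], marginals[j])
    return(x)
  }
  if (length(marginals) == 1L && length(z) > 1L) {
    u <- pmin(pmax(pnorm(z), .CDF_EPS), 1 - .CDF_EPS)
    return(marginal_quantile(marginals[[1L]], u))
  }
  if (length(z) != length(marginals))
    stop("length of 'z' must match the number of marginals")
  u <- pmin(pmax(pnorm(z), .CDF_EPS), 1 - .CDF_EPS)
  vapply(seq_along(z), function(j) marginal_quantile(marginals[[j]], u[j]),
         numeric(1))
}

#' Construct a Gaussian copula model
#'
#' Bundles a correlation matrix with one marginal distribution per column.
#' This is both the estimand of [gcm()] and the generative model used by
#' the synthetic-data designs.
#'
#' @param sigma p x p correlation matrix.
#' @param marginals list of p marginal objects (see [marginals]).
#' @param names optional column names.
#' @return an object of class `"gc_model"`.
#' @export
gc_model <- function(sigma, marginals, names = NULL) {
  sigma <- as.matrix(sigma)
  check_correlation(sigma)
  if (length(marginals) != nrow(sigma))
    stop("need one marginal per column of 'sigma'")
  if (is.null(names)) names <- colnames(sigma)
  if (is.null(names)) names <- paste0("X", seq_len(nrow(sigma)))
  dimnames(sigma) <- list(names, names)
  structure(list(sigma = sigma, marginals = marginals, names = names),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, digits = 4, ...) {
  p <- nrow(x$sigma)
  cat(sprintf("Gaussian copula model in %d dimensions\n", p))
  cat("Correlation matrix:\n")
  print(round(x$sigma, digits))
  cat("Marginals:\n")
  for (j in seq_len(p)) {
    cat(sprintf("  [%d] %s: ", j, x$names[j]))
    print(x$marginals[[j]])
  }
  invisible(x)
}

#' Joint log density of a Gaussian copula model
#'
#' Evaluates `-1/2 log|Sigma| - 1/2 z' (Sigma^{-1} - I) z + sum_j log f_j(x_j)`
#' with `z` the latent transform of `x`. Rows of a matrix `x` are evaluated
#' independently.
#'
#' @param x data-scale vector (length p) or matrix (n x p).
#' @param model a [gc_model()].
#' @return numeric vector of log densities.
#' @export
gc_log_density <- function(x, model) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  p <- nrow(model$sigma)
  if (ncol(x) != p) stop("'x' must have p columns")
  ch <- tryCatch(chol(model$sigma),
                 error = function(e) stop("'sigma' is singular or not PD"))
  logdet <- 2 * sum(log(diag(ch)))
  K <- chol2inv(ch)
  z <- to_latent(x, model$marginals)
  quad <- rowSums((z %*% (K - diag(p))) * z)
  marg <- 0
  for (j in seq_len(p))
    marg <- marg + log(marginal_density(model$marginals[[j]], x[, j]))
  -0.5 * logdet - 0.5 * quad + marg
}

#' Conditional latent-Gaussian parameters (Schur complement)
#'
#' Given the latent scores `z_S` of the observed columns `S`, returns the
#' mean and covariance of the latent scores of the remaining columns `T`:
#' `mu = Sigma[T,S] Sigma[S,S]^{-1} z_S`,
#' `Sigma' = Sigma[T,T] - Sigma[T,S] Sigma[S,S]^{-1} Sigma[S,T]`.
#' With `S` empty this is the unconditional `mu = 0`, `Sigma' = Sigma[T,T]`.
#'
#' @param z_s latent scores of the conditioning columns (length `|S|`).
#' @param sigma p x p correlation matrix.
#' @param S,T integer index sets (1-based); must be disjoint.
#' @return list with elements `mu` (length `|T|`) and `sigma_prime`
#'   (`|T| x |T|`, symmetrized and eigenvalue-clipped).
#' @export
conditional_params <- function(z_s, sigma, S, T) {
  S <- as.integer(S); T <- as.integer(T)
  if (length(intersect(S, T)) > 0L) stop("index sets 'S' and 'T' overlap")
  if (length(S) == 0L)
    return(list(mu = rep(0, length(T)),
                sigma_prime = psd_repair(sigma[T, T, drop = FALSE])))
  if (length(z_s) != length(S)) stop("'z_s' must have length |S|")
  Sss <- sigma[S, S, drop = FALSE]
  Sts <- sigma[T, S, drop = FALSE]
  A <- Sts %*% solve(Sss)
  mu <- drop(A %*% z_s)
  sp <- sigma[T, T, drop = FALSE] - A %*% t(Sts)
  list(mu = mu, sigma_prime = psd_repair(sp))
}

# draws n rows from N(mu, cov) via the Cholesky factor; cov must be PSD
rmvn <- function(n, mu, cov) {
  p <- length(mu)
  ch <- chol(psd_repair(cov))
  z <- matrix(rnorm(n * p), n, p) %*% ch
  sweep(z, 2L, mu, "+")
}

# log density of N(0, sigma) rows
dmvn0_log <- function(z, sigma) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  p <- ncol(z)
  ch <- chol(sigma)
  logdet <- 2 * sum(log(diag(ch)))
  quad <- rowSums((z %*% chol2inv(ch)) * z)
  -0.5 * (p * log(2 * pi) + logdet + quad)
}

#' Sample from the conditional distribution of a Gaussian copula
#'
#' Draws `m` joint samples of the columns `T` given observed data-scale
#' values `x_s` on columns `S`: transform to latent scores, draw from the
#' conditional normal of [conditional_params()], and map back through the
#' marginal quantile functions.
#'
#' @param x_s observed data-scale values on columns `S`.
#' @param model a [gc_model()].
#' @param T columns to sample (default: the complement of `S`).
#' @param S columns conditioned on.
#' @param m number of draws.
#' @return an `m x |T|` matrix of data-scale draws.
#' @export
sample_conditional <- function(x_s, model, S, T = setdiff(seq_len(nrow(model$sigma)), S),
                               m = 1L) {
  if (m < 1L) stop("'m' must be >= 1")
  z_s <- if (length(S)) to_latent(x_s, model$marginals[S]) else numeric(0)
  cp <- conditional_params(z_s, model$sigma, S, T)
  z <- rmvn(m, cp$mu, cp$sigma_prime)
  from_latent(z, model$marginals[T])
}

#' Sample complete observations from a Gaussian copula model
#'
#' Latent rows are drawn from `N(0, Sigma)` and mapped through the marginal
#' quantile functions, so each column follows its marginal and the latent
#' correlation is `Sigma`.
#'
#' @param model a [gc_model()].
#' @param n number of rows.
#' @return an `n x p` numeric matrix with the model's column names.
#' @export
sample_joint <- function(model, n) {
  p <- nrow(model$sigma)
  z <- rmvn(n, rep(0, p), model$sigma)
  x <- from_latent(z, model$marginals)
  colnames(x) <- model$names
  x
}

#' Test a conditional independence encoded in the precision matrix
#'
#' In a Gaussian copula, `(Sigma^{-1})[j,k] = 0` is equivalent to the
#' conditional independence of columns `j` and `k` given all others.
#'
#' @param sigma correlation matrix.
#' @param j,k column indices (1-based).
#' @param tol absolute tolerance on the precision entry.
#' @return `TRUE` iff the precision entry is below `tol` in magnitude.
#' @export
precision_zero <- function(sigma, j, k, tol = 1e-8) {
  K <- solve(sigma)
  abs(K[j, k]) < tol
}
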