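# E-step machinery: latent scores of the observed cells, the per-row
# conditional second-moment statistic, its pattern-grouped aggregation,
# and the observed-data Gaussian log-likelihood used as an EM diagnostic.

# latent matrix of the observed cells; NA stays NA at missing cells
latent_matrix <- function(x, marginals) {
  z <- matrix(NA_real_, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    oj <- !is.na(x[, j])
    if (any(oj)) z[oj, j] <- to_latent(x[oj, j], marginals[j])
  }
  z
}

#' Per-row conditional second-moment statistic
#'
#' For one observation with observed set `S` and missing set `T`, returns
#' the conditional expectation `V = E[z z' | z_S]` of the latent outer
#' product under the current model: `V[S,S] = z_S z_S'`,
#' `V[S,T] = z_S mu'`, `V[T,T] = Sigma' + mu mu'`, with `(mu, Sigma')`
#' from [conditional_params()]. A fully observed row gives the rank-one
#' `V = z z'`.
#'
#' @param x_row data-scale values of one row; `NA` marks missing cells.
#' @param marginals list of marginal objects (current theta).
#' @param sigma current correlation matrix.
#' @return a p x p symmetric matrix.
#' @export
row_statistic <- function(x_row, marginals, sigma) {
  p <- length(x_row)
  obs <- which(!is.na(x_row))
  mis <- setdiff(seq_len(p), obs)
  if (length(obs) == 0L) stop("row has no observed entries")
  z <- to_latent(x_row[obs], marginals[obs])
  V <- matrix(0, p, p)
  V[obs, obs] <- tcrossprod(z)
  if (length(mis)) {
    cp <- conditional_params(z, sigma, obs, mis)
    V[obs, mis] <- tcrossprod(z, cp$mu)
    V[mis, obs] <- t(V[obs, mis, drop = FALSE])
    V[mis, mis] <- cp$sigma_prime + tcrossprod(cp$mu)
  }
  V
}

#' Aggregated E-step sufficient statistic
#'
#' Averages the per-row conditional second-moment statistics,
#' `S = (1/N) sum_l V_l`. Rows sharing a missingness pattern share the
#' Schur-complement algebra, so the aggregation is grouped by pattern;
#' the result is identical to averaging [row_statistic()] over rows.
#'
#' @param z N x p latent matrix (`NA` at missing cells), i.e. the observed
#'   cells already transformed by the current marginals.
#' @param sigma current correlation matrix.
#' @return a p x p symmetric positive semi-definite matrix.
#' @export
estep_statistic <- function(z, sigma) {
  N <- nrow(z); p <- ncol(z)
  obs <- !is.na(z)
  if (any(rowSums(obs) == 0L)) stop("every row needs at least one observed entry")
  key <- apply(obs, 1L, function(r) paste0(as.integer(r), collapse = ""))
  Ssum <- matrix(0, p, p)
  for (k in unique(key)) {
    idx <- which(key == k)
    o <- obs[idx[1L], ]
    So <- which(o); Tm <- which(!o)
    Zo <- z[idx, So, drop = FALSE]
    Ssum[So, So] <- Ssum[So, So] + crossprod(Zo)
    if (length(Tm)) {
      A <- sigma[Tm, So, drop = FALSE] %*% solve(sigma[So, So, drop = FALSE])
      Mu <- Zo %*% t(A)                       # per-row conditional means
      Sp <- sigma[Tm, Tm, drop = FALSE] - A %*% sigma[So, Tm, drop = FALSE]
      Ssum[So, Tm] <- Ssum[So, Tm] + crossprod(Zo, Mu)
      Ssum[Tm, So] <- Ssum[Tm, So] + crossprod(Mu, Zo)
      Ssum[Tm, Tm] <- Ssum[Tm, Tm] + length(idx) * Sp + crossprod(Mu)
    }
  }
  S <- Ssum / N
  (S + t(S)) / 2
}

#' Correlation-normalized covariance update
#'
#' The conditional maximizer of the latent Gaussian likelihood over
#' unit-diagonal matrices is approximated by rescaling the sufficient
#' statistic to a correlation matrix: `P S P` with
#' `P_jj = 1/sqrt(S_jj)`. Scale-invariant: `sigma_update(a S)` equals
#' `sigma_update(S)` for any `a > 0`.
#'
#' @param S p x p sufficient statistic with positive diagonal.
#' @return a unit-diagonal correlation matrix.
#' @export
sigma_update <- function(S) {
  d <- diag(S)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("degenerate sufficient statistic: nonpositive diagonal entry at column ",
         which(!is.finite(d) | d <= 0)[1L])
  P <- 1 / sqrt(d)
  out <- S * tcrossprod(P)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Observed-data Gaussian log-likelihood of the latent scores
#'
#' With the marginals frozen, the observed cells of each row have latent
#' scores that are jointly normal with covariance the corresponding block
#' of `sigma`; this sums the row log-densities. It is an exact EM
#' objective for the correlation-only fit and is non-decreasing across
#' its iterations.
#'
#' @param z N x p latent matrix (`NA` at missing cells).
#' @param sigma correlation matrix.
#' @return the summed log-likelihood (a single number).
#' @export
observed_loglik_sigma <- function(z, sigma) {
  obs <- !is.na(z)
  key <- apply(obs, 1L, function(r) paste0(as.integer(r), collapse = ""))
  ll <- 0
  for (k in unique(key)) {
    idx <- which(key == k)
    So <- which(obs[idx[1L], ])
    ll <- ll + sum(dmvn0_log(z[idx, So, drop = FALSE],
                             sigma[So, So, drop = FALSE]))
  }
  ll
}

# correlation-only EM with frozen latent scores (SCOPE / known-marginals
# path, and the Sigma-part of the full ECM when marginals are frozen)
sigma_em <- function(z, tol = 1e-5, maxit = 500L, structure = NULL,
                     sigma0 = NULL, trace = TRUE) {
  p <- ncol(z)
  sigma <- if (is.null(sigma0)) diag(p) else sigma0
  updater <- if (is.null(structure)) sigma_update else
    function(S) constrained_sigma_update(S, structure)
  changes <- loglik <- numeric(0)
  converged <- FALSE
  for (t in seq_len(maxit)) {
    S <- estep_statistic(z, sigma)
    sigma_new <- updater(S)
    ch <- sum(abs(sigma_new - sigma))
    sigma <- sigma_new
    if (trace) {
      changes <- c(changes, ch)
      loglik <- c(loglik, observed_loglik_sigma(z, sigma))
    }
    if (ch < tol) { converged <- TRUE; break }
  }
  list(sigma = sigma, iterations = if (trace) length(changes) else t,
       converged = converged, sigma_change = changes, loglik = loglik)
}
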