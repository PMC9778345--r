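#' Control parameters for the ECM fit
#'
#' Defaults follow the reference run configuration: `g = 15` mixture
#' components, 20 burn-in steps with `M = 20` Monte Carlo completions per
#' incomplete row, then up to 5 steps with `M = 1000`, stopping when the
#' entrywise L1 change of the correlation matrix falls below `1e-5`.
#'
#' @param g number of mixture components per marginal.
#' @param M_small,steps_small Monte Carlo sample size and number of steps
#'   of the stabilization phase.
#' @param M_large,steps_large sample size and step cap of the refinement
#'   phase; the L1 stopping rule is checked in this phase.
#' @param tol L1 convergence threshold on the change of the correlation
#'   matrix between iterations.
#' @param max_sigma_steps iteration cap of the correlation-only fit used
#'   when the marginals are frozen.
#' @param optim_maxit_small,optim_maxit_large BFGS iteration caps for the
#'   marginal update in the two phases (a partial ascent preserves the
#'   ECM monotonicity, so small caps are safe).
#' @return a list of class `"gcm_control"`.
#' @export
gcm_control <- function(g = 15L, M_small = 20L, steps_small = 20L,
                        M_large = 1000L, steps_large = 5L, tol = 1e-5,
                        max_sigma_steps = 500L,
                        optim_maxit_small = 8L, optim_maxit_large = 10L) {
  stopifnot(g >= 1, M_small >= 1, steps_small >= 0, M_large >= 1,
            steps_large >= 0, tol > 0, max_sigma_steps >= 1)
  structure(list(g = as.integer(g), M_small = as.integer(M_small),
                 steps_small = as.integer(steps_small),
                 M_large = as.integer(M_large),
                 steps_large = as.integer(steps_large), tol = tol,
                 max_sigma_steps = as.integer(max_sigma_steps),
                 optim_maxit_small = as.integer(optim_maxit_small),
                 optim_maxit_large = as.integer(optim_maxit_large)),
            class = "gcm_control")
}

# validate the data matrix: numeric, every row with >= 1 observed cell,
# every column with >= 2 observed cells
check_missing_data <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'data' must be a numeric matrix or data frame")
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0L))
    stop("row ", which(rowSums(obs) == 0L)[1L], " has no observed entries")
  if (any(colSums(obs) < 2L))
    stop("column ", which(colSums(obs) < 2L)[1L], " has fewer than 2 observed entries")
  x
}

# deterministic per-(iteration, row) RNG substream so that row order does
# not change results; kept below 2^31
row_seed <- function(seed, iter, row) {
  as.integer((as.double(seed) * 48271 + iter * 69621 + row * 7919) %% 2147483587) + 1L
}

#' Monte Carlo completions of the missing cells
#'
#' For each row with missing entries, draws `M` completed rows whose
#' missing coordinates come from the conditional copula distribution
#' given the observed coordinates (under the current parameters); the
#' observed coordinates are repeated verbatim. Fully observed rows
#' contribute a single copy with weight 1; Monte Carlo copies carry
#' weight `1/M`, which reproduces the `(1/M) sum_l sum_m` weighting of
#' the Monte Carlo objective.
#'
#' @param x N x p data matrix with `NA` at missing cells.
#' @param model current [gc_model()].
#' @param M Monte Carlo sample size per incomplete row.
#' @param seed,iter master seed and iteration index for the per-row
#'   substreams (row order does not affect the draws).
#' @return list with `x` (stacked completed rows), `w` (weights) and
#'   `row` (originating row index).
#' @keywords internal
draw_completions <- function(x, model, M, seed = 1L, iter = 1L) {
  N <- nrow(x); p <- ncol(x)
  obs <- !is.na(x)
  incomplete <- which(rowSums(obs) < p)
  n_out <- (N - length(incomplete)) + length(incomplete) * M
  Xc <- matrix(0, n_out, p)
  w <- numeric(n_out)
  rid <- integer(n_out)
  pos <- 0L
  complete <- setdiff(seq_len(N), incomplete)
  if (length(complete)) {
    take <- seq_along(complete)
    Xc[take, ] <- x[complete, , drop = FALSE]
    w[take] <- 1
    rid[take] <- complete
    pos <- length(complete)
  }
  if (length(incomplete)) {
    z <- latent_matrix(x, model$marginals)
    Zc <- matrix(NA_real_, n_out, p)   # latent draws at the missing cells
    for (l in incomplete) {
      So <- which(obs[l, ]); Tm <- which(!obs[l, ])
      cp <- conditional_params(z[l, So], model$sigma, So, Tm)
      set.seed(row_seed(seed, iter, l))
      zdraw <- rmvn(M, cp$mu, cp$sigma_prime)
      block <- pos + seq_len(M)
      Xc[block, ] <- matrix(x[l, ], M, p, byrow = TRUE)
      Zc[block, Tm] <- zdraw
      w[block] <- 1 / M
      rid[block] <- l
      pos <- pos + M
    }
    # invert the marginal transform column-wise in one batch
    for (j in seq_len(p)) {
      fill <- which(!is.na(Zc[, j]))
      if (length(fill))
        Xc[fill, j] <- from_latent(Zc[fill, j], model$marginals[j])
    }
  }
  list(x = Xc, w = w, row = rid)
}

#' Monte Carlo objective of the marginal parameters
#'
#' The weighted completed-data objective maximized by the marginal
#' update: `sum_rows w * (-1/2 z' (K - I) z + sum_j log f_j(x_j))`, with
#' `z` the latent transform of the completed rows under the candidate
#' mixture means and `K` the precision of the updated correlation matrix.
#'
#' @param means g x p matrix of candidate mixture means (column j holds
#'   the means of marginal j).
#' @param sigmas length-p vector of fixed mixture bandwidths.
#' @param completions output of [draw_completions()] (or any list with
#'   `x` and `w`).
#' @param K_next precision matrix of the updated correlation matrix.
#' @return the objective value (a single number).
#' @export
theta_objective <- function(means, sigmas, completions, K_next) {
  ob <- make_theta_objective(completions$x, completions$w, K_next,
                             sigmas, nrow(as.matrix(means)))
  -ob$fn(as.numeric(means))
}

# negative objective and gradient closures for optim(); the fused
# value+gradient kernel is memoized on the parameter vector because BFGS
# evaluates both at the same iterate
make_theta_objective <- function(X, w, K, sigmas, g) {
  p <- ncol(X)
  last_par <- NULL
  last_eval <- NULL
  joint <- function(par) {
    if (!identical(par, last_par)) {
      last_eval <<- theta_obj_grad_cpp(X, w, K, sigmas, matrix(par, g, p))
      last_par <<- par
    }
    last_eval
  }
  list(fn = function(par) -joint(par)$value,
       gr = function(par) -as.numeric(joint(par)$grad))
}

# one conditional maximization of the mixture means (warm start at the
# current means, BFGS with analytic gradient, means sorted afterwards)
theta_update <- function(marginals, completions, K_next, maxit) {
  g <- length(marginals[[1L]]$means)
  p <- length(marginals)
  sigmas <- vapply(marginals, function(m) m$sigma, numeric(1))
  Th0 <- vapply(marginals, function(m) m$means, numeric(g))
  ob <- make_theta_objective(completions$x, completions$w, K_next, sigmas, g)
  fit <- tryCatch(
    optim(as.numeric(Th0), ob$fn, ob$gr, method = "BFGS",
          control = list(maxit = maxit, reltol = 1e-7)),
    error = function(e) NULL)
  par <- if (is.null(fit)) as.numeric(Th0) else fit$par
  # keep the ascent property even if the optimizer stepped badly
  if (ob$fn(par) > ob$fn(as.numeric(Th0))) par <- as.numeric(Th0)
  Th <- matrix(par, g, p)
  out <- lapply(seq_len(p), function(j) mixture_marginal(sort(Th[, j]), sigmas[j]))
  list(marginals = out, value = -ob$fn(par))
}

# Monte Carlo standard error of the full EM objective at the current
# parameters, from the completions already drawn: rows are independent and
# the within-row Monte Carlo variance of the row mean adds up
lambda_se <- function(completions, model) {
  ld <- gc_log_density(completions$x, model)
  per_row <- split(ld, completions$row)
  vr <- vapply(per_row, function(v)
    if (length(v) > 1L) var(v) / length(v) else 0, numeric(1))
  sqrt(sum(vr))
}

#' Fit a Gaussian copula model to data with missing values
#'
#' Estimates the copula correlation matrix and, optionally, semiparametric
#' Gaussian-mixture marginals by Expectation Conditional Maximization.
#' The E-step uses the exact conditional second-moment statistic of the
#' latent Gaussian scores; the correlation update rescales it to a
#' correlation matrix (or maximizes under precision-zero constraints when
#' `structure` is given); the marginal update maximizes a Monte Carlo
#' completed-data objective over the mixture means with the bandwidths
#' held fixed.
#'
#' Three variants are selected through `marginals`:
#' \describe{
#'   \item{`"mixture"`}{the full semiparametric fit: each marginal is an
#'     equal-weight Gaussian mixture initialized on the observed values
#'     and updated in the M-step.}
#'   \item{`"empirical"`}{the SCOPE baseline: marginals frozen at the
#'     rescaled empirical distribution of the observed values; only the
#'     correlation matrix is estimated.}
#'   \item{a list of marginal objects}{known-marginals baseline: the
#'     provided truths are frozen and only the correlation is estimated.}
#' }
#'
#' @param data numeric matrix or data frame; `NA` marks a missing cell.
#'   Every row needs at least one observed cell and every column at
#'   least two.
#' @param marginals `"mixture"`, `"empirical"`, or a list of p marginal
#'   objects (see [marginals]).
#' @param structure optional precision-zero constraints (pairs of 1-based
#'   column indices; see [constrained_sigma_update()]).
#' @param control a [gcm_control()] list.
#' @param seed integer master seed for the Monte Carlo draws; every
#'   source of randomness in the fit flows from it.
#' @return an object of class `"gcm"`: the fitted [gc_model()] plus the
#'   iteration trajectory. Supported methods include `print`, `summary`,
#'   `coef`, `predict`, `plot`, `simulate`, `residuals` and `logLik`.
#' @examples
#' d <- design_2d(N = 80)
#' x <- simulate_design(d, seed = 7)$data
#' fit <- gcm(x, marginals = "empirical")
#' coef(fit)
#' @export
gcm <- function(data, marginals = c("mixture", "empirical"), structure = NULL,
                control = gcm_control(), seed = 1L) {
  cl <- match.call()
  x <- check_missing_data(data)
  p <- ncol(x); N <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(p))
  if (!is.null(structure)) normalize_structure(structure, p)

  frozen <- !(is.character(marginals) && marginals[1L] == "mixture")
  if (is.character(marginals)) {
    marginals <- match.arg(marginals)
    marg_list <- switch(marginals,
      mixture = lapply(seq_len(p), function(j)
        init_mixture(x[, j][!is.na(x[, j])], g = control$g)),
      empirical = lapply(seq_len(p), function(j)
        empirical_marginal(x[, j])))
    method <- if (frozen) "scope" else "em"
  } else {
    if (!is.list(marginals) || length(marginals) != p ||
        !all(vapply(marginals, inherits, logical(1), "gc_marginal")))
      stop("'marginals' must be \"mixture\", \"empirical\", or a list of p marginal objects")
    marg_list <- marginals
    method <- "known"
  }
  if (!is.null(structure) && method != "em") method <- paste0("kp_", method)
  if (!is.null(structure) && method == "em") method <- "kp_em"

  if (frozen) {
    z <- latent_matrix(x, marg_list)
    res <- sigma_em(z, tol = control$tol, maxit = control$max_sigma_steps,
                    structure = structure)
    traj <- data.frame(iter = seq_along(res$sigma_change), M = 0L,
                       sigma_change = res$sigma_change,
                       objective = res$loglik, objective_se = 0)
    out <- list(model = gc_model(res$sigma, marg_list, colnames(x)),
                method = method, converged = res$converged,
                iterations = res$iterations, trajectory = traj,
                structure = structure, control = control, seed = seed,
                data = x, call = cl)
    class(out) <- "gcm"
    return(out)
  }

  # full ECM with mixture marginals
  set.seed(seed)
  sigma <- diag(p)
  schedule <- c(rep(control$M_small, control$steps_small),
                rep(control$M_large, control$steps_large))
  maxits <- c(rep(control$optim_maxit_small, control$steps_small),
              rep(control$optim_maxit_large, control$steps_large))
  traj <- data.frame(iter = integer(0), M = integer(0),
                     sigma_change = numeric(0), objective = numeric(0),
                     objective_se = numeric(0))
  converged <- FALSE
  for (t in seq_along(schedule)) {
    M <- schedule[t]
    model_t <- gc_model(sigma, marg_list, colnames(x))
    z <- latent_matrix(x, marg_list)
    S <- estep_statistic(z, sigma)
    sigma_new <- if (is.null(structure)) sigma_update(S) else
      constrained_sigma_update(S, structure)
    if (any(!is.finite(sigma_new)))
      stop("non-finite correlation update at iteration ", t)
    comps <- draw_completions(x, model_t, M, seed = seed, iter = t)
    K_next <- solve(sigma_new)
    up <- theta_update(marg_list, comps, K_next, maxit = maxits[t])
    marg_list <- up$marginals
    ch <- sum(abs(sigma_new - sigma))
    sigma <- sigma_new
    # Monte Carlo estimate of the full EM objective at (theta_{t+1},
    # Sigma_{t+1}); the theta objective already holds everything but the
    # log-determinant term. The (costlier) standard error is evaluated in
    # the large-M phase, where the monotonicity diagnostic lives.
    lam <- up$value - 0.5 * N * determinant(sigma, logarithm = TRUE)$modulus
    se <- if (M >= control$M_large)
      lambda_se(comps, gc_model(sigma, marg_list, colnames(x))) else NA_real_
    traj <- rbind(traj, data.frame(iter = t, M = M, sigma_change = ch,
                                   objective = as.numeric(lam),
                                   objective_se = se))
    if (M >= control$M_large && ch < control$tol) { converged <- TRUE; break }
  }
  out <- list(model = gc_model(sigma, marg_list, colnames(x)),
              method = method, converged = converged,
              iterations = nrow(traj), trajectory = traj,
              structure = structure, control = control, seed = seed,
              data = x, call = cl)
  class(out) <- "gcm"
  out
}
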