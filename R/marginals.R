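#' Marginal distribution objects
#'
#' One-dimensional marginal models used inside a Gaussian copula:
#' an equal-weight Gaussian mixture with common bandwidth (the
#' semiparametric family updated by the ECM algorithm), parametric
#' families used as simulation truths, and the rescaled empirical
#' distribution used by the SCOPE baseline.
#'
#' Every marginal answers [marginal_cdf()], [marginal_density()] and
#' [marginal_quantile()]. The cdf is strictly increasing on the support,
#' so quantile and cdf are mutual inverses up to numerical tolerance.
#'
#' @param means numeric vector of mixture component means; stored sorted.
#' @param sigma common component standard deviation (bandwidth), `> 0`.
#' @name marginals
NULL

#' @describeIn marginals Equal-weight Gaussian mixture marginal with `g`
#'   components at `means` and common bandwidth `sigma`.
#' @export
mixture_marginal <- function(means, sigma) {
  means <- as.numeric(means)
  if (length(means) < 1L || anyNA(means))
    stop("'means' must be a non-empty numeric vector")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  structure(list(means = sort(means), sigma = as.numeric(sigma)),
            class = c("mixture_marginal", "gc_marginal"))
}

#' @describeIn marginals Chi-square marginal with `df` degrees of freedom.
#' @param df positive degrees of freedom.
#' @export
chisq_marginal <- function(df) {
  if (!is.numeric(df) || length(df) != 1L || df <= 0)
    stop("'df' must be a single positive number")
  structure(list(df = as.numeric(df)),
            class = c("chisq_marginal", "gc_marginal"))
}

#' @describeIn marginals Normal marginal (used mainly in tests and as a
#'   simulation truth).
#' @param mean,sd location and scale of the normal marginal.
#' @export
normal_marginal <- function(mean = 0, sd = 1) {
  if (sd <= 0) stop("'sd' must be positive")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = c("normal_marginal", "gc_marginal"))
}

#' @describeIn marginals Rescaled empirical distribution of the observed
#'   values of one column: the ecdf multiplied by `n/(n+1)` and floored at
#'   `1/(n+1)`, so its values stay strictly inside (0,1) and the normal
#'   quantile transform is always finite (pseudo-observation convention).
#' @param values observed (non-missing) numeric values.
#' @export
empirical_marginal <- function(values) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) == 0L) stop("'values' must contain at least one observation")
  structure(list(values = sort(values), n = length(values)),
            class = c("empirical_marginal", "gc_marginal"))
}

#' Evaluate a marginal distribution
#'
#' @param m a marginal object (see [marginals]).
#' @param x numeric vector of data-scale values.
#' @return `marginal_cdf` returns probabilities in (0,1) (the empirical
#'   marginal is rescaled away from the boundary); `marginal_density`
#'   non-negative densities; `marginal_quantile` data-scale values.
#' @export
marginal_cdf <- function(m, x) UseMethod("marginal_cdf")

#' @rdname marginal_cdf
#' @export
marginal_density <- function(m, x) UseMethod("marginal_density")

#' @rdname marginal_cdf
#' @param u probabilities strictly inside (0,1).
#' @export
marginal_quantile <- function(m, u) UseMethod("marginal_quantile")

#' @export
marginal_cdf.mixture_marginal <- function(m, x) {
  mix_eval_cpp(as.numeric(x), m$means, m$sigma)$cdf
}

#' @export
marginal_density.mixture_marginal <- function(m, x) {
  mix_eval_cpp(as.numeric(x), m$means, m$sigma)$pdf
}

#' @export
marginal_quantile.mixture_marginal <- function(m, u) {
  check_unit_interval(u)
  # safeguarded Newton, bracketed by the quantiles of the extreme
  # components: F is bounded between the cdfs of the extreme components,
  # so the root lies in [min(means), max(means)] + sigma*qnorm(u)
  mix_quantile_cpp(as.numeric(u), m$means, m$sigma)
}

#' @export
marginal_cdf.chisq_marginal <- function(m, x) pchisq(x, df = m$df)

#' @export
marginal_density.chisq_marginal <- function(m, x) dchisq(x, df = m$df)

#' @export
marginal_quantile.chisq_marginal <- function(m, u) {
  check_unit_interval(u)
  qchisq(u, df = m$df)
}

#' @export
marginal_cdf.normal_marginal <- function(m, x) pnorm(x, m$mean, m$sd)

#' @export
marginal_density.normal_marginal <- function(m, x) dnorm(x, m$mean, m$sd)

#' @export
marginal_quantile.normal_marginal <- function(m, u) {
  check_unit_interval(u)
  qnorm(u, m$mean, m$sd)
}

#' @export
marginal_cdf.empirical_marginal <- function(m, x) {
  n <- m$n
  k <- findInterval(x, m$values)          # #{v <= x}
  pmax(k / (n + 1), 1 / (n + 1))
}

#' @export
marginal_density.empirical_marginal <- function(m, x) {
  stop("the rescaled empirical marginal has no density; ",
       "density-based quantities are undefined for it")
}

#' @export
marginal_quantile.empirical_marginal <- function(m, u) {
  check_unit_interval(u)
  n <- m$n
  # generalized inverse of the rescaled step function
  k <- pmin(pmax(ceiling(u * (n + 1)), 1L), n)
  m$values[k]
}

check_unit_interval <- function(u) {
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  invisible(u)
}

#' @export
print.gc_marginal <- function(x, ...) {
  if (inherits(x, "mixture_marginal")) {
    cat(sprintf("Gaussian mixture marginal: g = %d, bandwidth sigma = %.4g\n",
                length(x$means), x$sigma))
    cat("means:", format(x$means, digits = 4), "\n")
  } else if (inherits(x, "chisq_marginal")) {
    cat(sprintf("Chi-square marginal, df = %g\n", x$df))
  } else if (inherits(x, "normal_marginal")) {
    cat(sprintf("Normal marginal, mean = %g, sd = %g\n", x$mean, x$sd))
  } else {
    cat(sprintf("Rescaled empirical marginal on %d observed values\n", x$n))
  }
  invisible(x)
}

#' Rule-of-thumb bandwidth for the mixture marginal
#'
#' Silverman-type rule: `1.06 * sd / g^(1/5)`, where `sd` is the standard
#' deviation of the observed values of the column and `g` the number of
#' mixture components. As `g` approaches the sample size the mixture
#' approaches a kernel density estimate with this bandwidth.
#'
#' @param sd_observed standard deviation of the observed values, `> 0`.
#' @param g number of mixture components, `>= 1`.
#' @return the common component standard deviation.
#' @export
bandwidth_rule <- function(sd_observed, g) {
  if (!is.numeric(sd_observed) || length(sd_observed) != 1L ||
      !is.finite(sd_observed) || sd_observed <= 0)
    stop("'sd_observed' must be a single positive number")
  if (g < 1) stop("'g' must be >= 1")
  1.06 * sd_observed / g^(1 / 5)
}

#' Initialize a mixture marginal from observed values
#'
#' Places the `g` component means at the `(k - 0.5)/g` empirical quantiles
#' of the observed values, sets the bandwidth by [bandwidth_rule()], and
#' refines the means by least squares between the mixture cdf and the
#' empirical cdf evaluated at the observed points. The refined means are
#' returned sorted (the mixture is exchangeable in its components, so
#' sorting is a pure relabelling that fixes identifiability).
#'
#' @param values observed numeric values (at least `g` of them).
#' @param g number of mixture components.
#' @param refine if `FALSE`, skip the least-squares refinement.
#' @return a [mixture_marginal()].
#' @export
init_mixture <- function(values, g = 15L, refine = TRUE) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < g)
    stop(sprintf("need at least g = %d observed values, got %d", g, length(values)))
  sdv <- sd(values)
  if (!is.finite(sdv) || sdv <= 0)
    stop("observed values are constant; cannot set a bandwidth")
  sigma <- bandwidth_rule(sdv, g)
  means0 <- as.numeric(quantile(values, probs = (seq_len(g) - 0.5) / g,
                                type = 7, names = FALSE))
  if (!refine) return(mixture_marginal(means0, sigma))
  xs <- sort(values)
  n <- length(xs)
  ec <- seq_len(n) / (n + 1)           # rescaled ecdf at the sorted points
  obj <- function(th) {
    mm <- mixture_marginal(th, sigma)
    sum((marginal_cdf(mm, xs) - ec)^2)
  }
  grad <- function(th) {
    # d/d th_k sum (F(x)-ec)^2 = sum 2 (F-ec) * (-(1/g) dnorm((x-th_k)/s)/s)
    tmat <- outer(xs, th, function(x, t) (x - t) / sigma)
    Fm <- rowMeans(pnorm(tmat))
    r <- 2 * (Fm - ec)
    -colSums(r * dnorm(tmat)) / (g * sigma)
  }
  fit <- optim(means0, obj, grad, method = "BFGS",
               control = list(maxit = 100, reltol = 1e-10))
  mixture_marginal(sort(fit$par), sigma)
}
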