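# S3 methods for fitted "gcm" objects

#' @export
print.gcm <- function(x, digits = 4, ...) {
  cat(sprintf("Gaussian copula fit (%s), %d x %d data, %d missing cells (%.1f%%)\n",
              x$method, nrow(x$data), ncol(x$data), sum(is.na(x$data)),
              100 * mean(is.na(x$data))))
  cat(sprintf("%d iterations, %sconverged (final L1 change %.3g)\n",
              x$iterations, if (x$converged) "" else "NOT ",
              utils::tail(x$trajectory$sigma_change, 1)))
  cat("Correlation matrix:\n")
  print(round(x$model$sigma, digits))
  invisible(x)
}

#' @export
summary.gcm <- function(object, ...) {
  structure(list(fit = object), class = "summary.gcm")
}

#' @export
print.summary.gcm <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (!is.null(f$structure)) {
    pairs <- normalize_structure(f$structure, ncol(f$data))
    cat("Precision zeros enforced on pairs:",
        paste(apply(pairs, 1, paste, collapse = "-"), collapse = ", "), "\n")
    cat("Constraints satisfied:", verify_structure(f$model$sigma, f$structure), "\n")
  }
  cat("Marginals:\n")
  for (j in seq_len(ncol(f$data))) {
    cat(sprintf("  [%d] %s: ", j, f$model$names[j]))
    print(f$model$marginals[[j]])
  }
  cat("Iteration trajectory (last rows):\n")
  print(utils::tail(f$trajectory, 5), digits = digits)
  invisible(x)
}

#' @export
coef.gcm <- function(object, ...) {
  s <- object$model$sigma
  p <- nrow(s)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  out <- s[upper.tri(s)]
  names(out) <- paste0("rho_", idx[, 1], idx[, 2])
  out
}

#' @export
simulate.gcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sample_joint(object$model, nsim)
}

#' Latent-score residuals of a Gaussian copula fit
#'
#' Returns the latent normal scores `qnorm(F_j(x_j))` of the observed
#' cells under the fitted marginals (`NA` at missing cells). Under a
#' correct fit each column is approximately standard normal with the
#' fitted latent correlation.
#'
#' @param object a fitted `"gcm"` object.
#' @param ... unused.
#' @export
residuals.gcm <- function(object, ...) {
  z <- latent_matrix(object$data, object$model$marginals)
  dimnames(z) <- dimnames(object$data)
  z
}

#' @export
logLik.gcm <- function(object, ...) {
  z <- latent_matrix(object$data, object$model$marginals)
  ll <- observed_loglik_sigma(z, object$model$sigma)
  p <- ncol(object$data)
  df <- p * (p - 1) / 2 +
    if (object$method %in% c("em", "kp_em")) p * object$control$g else 0
  structure(ll, df = df, nobs = nrow(object$data), class = "logLik")
}

#' Predict (impute) missing cells from a Gaussian copula fit
#'
#' For each row of `newdata` with missing cells, draws from the fitted
#' conditional distribution of the missing columns given the observed
#' ones and returns either the Monte Carlo conditional expectation
#' (`type = "expectation"`) or one sampled completion (`type = "sample"`).
#' Observed cells are passed through unchanged.
#'
#' @param object a fitted `"gcm"` object.
#' @param newdata matrix/data frame with `NA` at cells to impute;
#'   defaults to the training data.
#' @param type `"expectation"` or `"sample"`.
#' @param M Monte Carlo draws per row for the expectation.
#' @param seed optional seed.
#' @param ... unused.
#' @return a completed numeric matrix.
#' @export
predict.gcm <- function(object, newdata = NULL, type = c("expectation", "sample"),
                        M = 100L, seed = NULL, ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$data else check_missing_data(newdata)
  if (ncol(x) != ncol(object$data)) stop("'newdata' has the wrong number of columns")
  if (!is.null(seed)) set.seed(seed)
  out <- x
  for (l in which(rowSums(is.na(x)) > 0)) {
    So <- which(!is.na(x[l, ])); Tm <- which(is.na(x[l, ]))
    draws <- sample_conditional(x[l, So], object$model, S = So, T = Tm,
                                m = if (type == "expectation") M else 1L)
    out[l, Tm] <- if (type == "expectation") colMeans(draws) else draws[1L, ]
  }
  out
}

#' Plot a Gaussian copula fit
#'
#' One panel per column comparing the fitted marginal cdf with the
#' rescaled empirical cdf of the observed values. Under missingness at
#' random the two may differ visibly: the observed-data ecdf is a biased
#' estimate of the marginal while the model-based fit corrects through
#' the dependence structure.
#'
#' @param x a fitted `"gcm"` object.
#' @param which columns to plot (default: all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gcm <- function(x, which = seq_len(ncol(x$data)), ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  for (j in which) {
    v <- x$data[, j]; v <- v[!is.na(v)]
    grid <- seq(min(v) - sd(v), max(v) + sd(v), length.out = 200)
    em <- empirical_marginal(v)
    graphics::plot(grid, marginal_cdf(x$model$marginals[[j]], grid), type = "l",
                   xlab = x$model$names[j], ylab = "cdf",
                   main = sprintf("%s marginal", x$model$names[j]), ...)
    graphics::lines(grid, marginal_cdf(em, grid), lty = 2, col = "grey40")
    graphics::legend("bottomright", c("fitted", "observed ecdf"),
                     lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  }
  invisible(x)
}
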