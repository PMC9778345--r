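#' Cramer-von Mises distance between an estimated and a true marginal
#'
#' The integrated squared difference `c * integral (Fhat - F)^2 dF`,
#' computed by quadrature after substituting `u = F(x)` on an equispaced
#' grid in (0,1). The scaling constant `c` is a reporting convention; the
#' default 1000 matches the magnitudes customary in simulation tables,
#' but comparisons between methods are invariant to it.
#'
#' @param f_hat estimated marginal: a marginal object or a vectorized cdf
#'   function.
#' @param f_true true marginal (must support [marginal_quantile()]).
#' @param scale the constant `c`.
#' @param n_grid number of quadrature points.
#' @return the statistic (a single number).
#' @export
cramer_von_mises <- function(f_hat, f_true, scale = 1000, n_grid = 2000L) {
  u <- (seq_len(n_grid) - 0.5) / n_grid
  x <- marginal_quantile(f_true, u)
  fh <- if (is.function(f_hat)) f_hat(x) else marginal_cdf(f_hat, x)
  scale * mean((fh - u)^2)
}

#' Frobenius norm of a correlation estimation error
#'
#' @param sigma_hat,sigma_true matrices of identical dimensions.
#' @return `||sigma_hat - sigma_true||_F`.
#' @export
frobenius_error <- function(sigma_hat, sigma_true) {
  if (!all(dim(sigma_hat) == dim(sigma_true)))
    stop("matrices must have identical dimensions")
  sqrt(sum((sigma_hat - sigma_true)^2))
}

#' Monte Carlo Kullback-Leibler divergence between two copula models
#'
#' Estimates `KL(true || hat) = E_true[log f_true(X) - log f_hat(X)]` by
#' averaging the log-density ratio over `n` draws from the true model.
#' Both models need densities (the rescaled empirical marginal has none,
#' so divergences involving it are undefined and refused upstream).
#'
#' @param model_true,model_hat [gc_model()] objects with density-bearing
#'   marginals.
#' @param n Monte Carlo sample size.
#' @param seed optional seed.
#' @return list with `estimate`, Monte Carlo `se`, and `n`.
#' @export
kl_divergence <- function(model_true, model_hat, n = 5000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sample_joint(model_true, n)
  ratio <- gc_log_density(x, model_true) - gc_log_density(x, model_hat)
  if (any(!is.finite(ratio)))
    stop("non-finite log-density ratio at draw ", which(!is.finite(ratio))[1L])
  list(estimate = mean(ratio), se = sd(ratio) / sqrt(n), n = n)
}

#' Replicated simulation study over a design
#'
#' Generates `reps` independent datasets from `design` and applies each
#' requested estimator, collecting the estimated correlation (off-diagonal
#' for the two-dimensional design), the Cramer-von Mises distance of every
#' density-bearing or empirical marginal estimate to the truth, the
#' Frobenius error of the correlation matrix, and (for the mixture-based
#' fits, when `kl_n > 0`) the Kullback-Leibler divergence from the truth.
#'
#' @param design a [design_2d()] or [design_3d()].
#' @param methods subset of `"known"`, `"scope"`, `"em"`, `"kp_em"`
#'   (`"kp_em"` uses the design's known precision zero and is only
#'   meaningful for the three-dimensional design).
#' @param reps number of replicates.
#' @param seed master seed; replicate `r` uses `seed + r`.
#' @param control [gcm_control()] passed to the fits.
#' @param kl_n Monte Carlo sample size for the divergence (0 disables it).
#' @return an object of class `"gc_replication"`: a long data frame
#'   `results` (`rep`, `method`, `metric`, `value`), the failure count,
#'   and a `summary()`/`print()` view of means and standard deviations.
#' @export
replicate_study <- function(design, methods = c("known", "scope"), reps = 100L,
                            seed = 1L, control = gcm_control(), kl_n = 0L) {
  stopifnot(reps >= 1)
  methods <- match.arg(methods, c("known", "scope", "em", "kp_em"),
                       several.ok = TRUE)
  structure3d <- if (design$type == "3d") matrix(c(2L, 3L), 1, 2) else NULL
  rows <- list(); failures <- 0L
  for (r in seq_len(reps)) {
    dat <- simulate_design(design, seed = seed + r)
    x <- dat$data
    truth <- design$model
    for (meth in methods) {
      fit <- tryCatch(switch(meth,
        known = gcm(x, marginals = truth$marginals, control = control,
                    seed = seed + r),
        scope = gcm(x, marginals = "empirical", control = control,
                    seed = seed + r),
        em    = gcm(x, marginals = "mixture", control = control,
                    seed = seed + r),
        kp_em = gcm(x, marginals = "mixture", structure = structure3d,
                    control = control, seed = seed + r)),
        error = function(e) NULL)
      if (is.null(fit)) { failures <- failures + 1L; next }
      vals <- list()
      if (design$type == "2d")
        vals$rho <- fit$model$sigma[1, 2]
      vals$frobenius <- frobenius_error(fit$model$sigma, truth$sigma)
      if (meth != "known") {
        for (j in seq_len(ncol(x)))
          vals[[paste0("omega", j)]] <-
            cramer_von_mises(fit$model$marginals[[j]], truth$marginals[[j]])
      }
      if (kl_n > 0 && meth %in% c("em", "kp_em")) {
        kl <- tryCatch(kl_divergence(truth, fit$model, n = kl_n,
                                     seed = seed + r),
                       error = function(e) NULL)
        if (!is.null(kl)) vals$kl <- kl$estimate
      }
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, method = meth, metric = names(vals),
                   value = unlist(vals, use.names = FALSE))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, design = design, reps = reps,
                 seed = seed, failures = failures),
            class = "gc_replication")
}

#' @export
summary.gc_replication <- function(object, ...) {
  ag <- aggregate(value ~ method + metric, data = object$results,
                  FUN = function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
  out <- data.frame(method = ag$method, metric = ag$metric,
                    mean = ag$value[, "mean"], sd = ag$value[, "sd"],
                    n = ag$value[, "n"])
  out[order(out$metric, out$method), ]
}

#' @export
print.gc_replication <- function(x, digits = 4, ...) {
  cat(sprintf("Replication study: %d replicates, seed %d, %d failures\n",
              x$reps, x$seed, x$failures))
  print(x$design)
  print(summary(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @describeIn replicate_study one boxplot panel per metric, methods side
#'   by side.
#' @param x a `"gc_replication"` object.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.gc_replication <- function(x, ...) {
  metrics <- unique(x$results$metric)
  op <- graphics::par(mfrow = c(1, length(metrics)))
  on.exit(graphics::par(op))
  for (m in metrics) {
    r <- x$results[x$results$metric == m, ]
    graphics::boxplot(value ~ method, data = r, main = m,
                      xlab = "", ylab = m, ...)
  }
  invisible(x)
}

#' Extract a per-replicate metric vector from a replication study
#'
#' @param study a `"gc_replication"` object.
#' @param method,metric selectors matching the `results` columns.
#' @return numeric vector of per-replicate values.
#' @export
replication_values <- function(study, method, metric) {
  r <- study$results
  r$value[r$method == method & r$metric == metric]
}
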