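#' Synthetic-data designs with missing-at-random mechanisms
#'
#' Two reference designs used throughout the package's simulation
#' studies. `design_2d` couples chi-square marginals (6 and 7 degrees of
#' freedom) through a Gaussian copula with correlation `rho`, thins every
#' cell completely at random with probability `p_mcar`, and then masks
#' column 2 of the still-complete rows with the logistic
#' missing-at-random probability
#' `1/(1 + exp(-beta0 - beta1 * qnorm(F1(x1))))`, which depends only on
#' the observed first column. `design_3d` uses chi-square marginals with
#' 6, 7 and 5 degrees of freedom and the correlation matrix implied by
#' the precision pattern `[[1,.5,.5],[.5,1,0],[.5,0,1]]` (so columns 2
#' and 3 are conditionally independent given column 1); columns 1-2 are
#' thinned completely at random and column 3 is masked, when columns 1-2
#' are observed, with logistic probability in both latent scores.
#'
#' @param N number of rows.
#' @param rho copula correlation of the two-dimensional design.
#' @param beta0,beta1,beta2 logistic missingness coefficients.
#' @param p_mcar completely-at-random cell-deletion probability. Not
#'   dictated by the reference study configuration; the default 0.1 is a
#'   small thinning layer so that every column can be missing.
#' @param dofs chi-square degrees of freedom per column.
#' @return a list of class `"gc_design"` holding the true [gc_model()]
#'   and the mechanism parameters.
#' @export
design_2d <- function(N = 100, rho = 0.5, beta0 = 0, beta1 = 2,
                      p_mcar = 0.1, dofs = c(6, 7)) {
  stopifnot(N >= 1, abs(rho) < 1, p_mcar >= 0, p_mcar < 1, length(dofs) == 2)
  sigma <- matrix(c(1, rho, rho, 1), 2, 2)
  model <- gc_model(sigma, lapply(dofs, chisq_marginal))
  structure(list(type = "2d", N = N, rho = rho, beta0 = beta0, beta1 = beta1,
                 p_mcar = p_mcar, dofs = dofs, model = model),
            class = "gc_design")
}

#' @rdname design_2d
#' @export
design_3d <- function(N = 50, dofs = c(6, 7, 5), p_mcar = 0.1,
                      beta0 = 0, beta1 = 1, beta2 = 1) {
  stopifnot(N >= 1, p_mcar >= 0, p_mcar < 1, length(dofs) == 3)
  sigma <- build_sigma_3d()
  model <- gc_model(sigma, lapply(dofs, chisq_marginal))
  structure(list(type = "3d", N = N, beta0 = beta0, beta1 = beta1,
                 beta2 = beta2, p_mcar = p_mcar, dofs = dofs, model = model),
            class = "gc_design")
}

#' @export
print.gc_design <- function(x, ...) {
  cat(sprintf("%s design: N = %d, chi-square dof (%s), p_mcar = %g\n",
              x$type, x$N, paste(x$dofs, collapse = ", "), x$p_mcar))
  if (x$type == "2d")
    cat(sprintf("rho = %g, logistic MAR beta = (%g, %g) on column 2\n",
                x$rho, x$beta0, x$beta1))
  else
    cat(sprintf("precision zero (2,3); logistic MAR beta = (%g, %g, %g) on column 3\n",
                x$beta0, x$beta1, x$beta2))
  invisible(x)
}

#' Correlation matrix of the three-dimensional design
#'
#' Starts from the base precision pattern
#' `K0 = [[1, .5, .5], [.5, 1, 0], [.5, 0, 1]]`, inverts it, and rescales
#' with the diagonal so the result has unit diagonal. The zero at (2,3)
#' survives the diagonal rescaling, so `(Sigma^{-1})[2,3] = 0`:
#' columns 2 and 3 are conditionally independent given column 1.
#'
#' @return a 3 x 3 correlation matrix.
#' @export
build_sigma_3d <- function() {
  K0 <- matrix(c(1, .5, .5,
                 .5, 1, 0,
                 .5, 0, 1), 3, 3, byrow = TRUE)
  S0 <- solve(K0)
  D <- diag(1 / sqrt(diag(S0)))
  sigma <- D %*% S0 %*% D
  sigma <- (sigma + t(sigma)) / 2
  diag(sigma) <- 1
  sigma
}

#' Apply missingness mechanisms to a complete table
#'
#' `apply_mcar` masks every cell independently with probability `p_mcar`;
#' rows losing all entries are dropped (their count is recorded in the
#' `"dropped"` attribute). `apply_mar_2d` then masks column 2 of rows
#' whose both entries are still observed, with the logistic probability
#' driven by the latent score of column 1; `apply_mar_3d` masks column 3
#' of rows whose columns 1-2 are observed, driven by both latent scores.
#' Both logistic mechanisms depend only on values that remain observed,
#' so the combined mechanism is missing at random.
#'
#' @param x complete (or partially masked) numeric matrix.
#' @param p_mcar cell deletion probability in `[0, 1)`.
#' @param design a [design_2d()] / [design_3d()] carrying the mechanism
#'   parameters and the true marginals.
#' @return the matrix with `NA` at masked cells.
#' @export
apply_mcar <- function(x, p_mcar) {
  stopifnot(p_mcar >= 0, p_mcar < 1)
  if (p_mcar > 0) {
    mask <- matrix(runif(length(x)) < p_mcar, nrow(x), ncol(x))
    x[mask] <- NA_real_
  }
  empty <- rowSums(!is.na(x)) == 0L
  if (any(empty)) x <- x[!empty, , drop = FALSE]
  attr(x, "dropped") <- sum(empty)
  x
}

#' @rdname apply_mcar
#' @export
apply_mar_2d <- function(x, design) {
  stopifnot(design$type == "2d")
  both <- which(!is.na(x[, 1]) & !is.na(x[, 2]))
  if (length(both)) {
    z1 <- to_latent(x[both, 1], design$model$marginals[1])
    pmiss <- plogis(design$beta0 + design$beta1 * z1)
    x[both[runif(length(both)) < pmiss], 2] <- NA_real_
  }
  x
}

#' @rdname apply_mcar
#' @export
apply_mar_3d <- function(x, design) {
  stopifnot(design$type == "3d")
  ok <- which(!is.na(x[, 1]) & !is.na(x[, 2]) & !is.na(x[, 3]))
  if (length(ok)) {
    z1 <- to_latent(x[ok, 1], design$model$marginals[1])
    z2 <- to_latent(x[ok, 2], design$model$marginals[2])
    pmiss <- plogis(design$beta0 + design$beta1 * z1 + design$beta2 * z2)
    x[ok[runif(length(ok)) < pmiss], 3] <- NA_real_
  }
  x
}

#' Generate one dataset from a design
#'
#' Draws a complete table from the design's Gaussian copula model,
#' applies the completely-at-random thinning and then the logistic
#' missing-at-random mechanism. In the three-dimensional design the
#' thinning applies to columns 1-2 only, matching the mechanism
#' description (the missingness of column 3 is purely the logistic one).
#'
#' @param design a [design_2d()] or [design_3d()].
#' @param seed optional integer seed (a pure function of (design, seed)).
#' @return list with `data` (masked matrix), `complete` (the underlying
#'   complete table) and `model` (the true [gc_model()]).
#' @export
simulate_design <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sample_joint(design$model, design$N)
  if (design$type == "2d") {
    xm <- apply_mcar(x, design$p_mcar)
    xm <- apply_mar_2d(xm, design)
  } else {
    xm <- x
    if (design$p_mcar > 0) {
      mask <- matrix(runif(2L * nrow(xm)) < design$p_mcar, nrow(xm), 2L)
      xm[, 1:2][mask] <- NA_real_
    }
    xm <- apply_mar_3d(xm, design)
    empty <- rowSums(!is.na(xm)) == 0L
    if (any(empty)) xm <- xm[!empty, , drop = FALSE]
  }
  dropped <- attr(xm, "dropped"); attr(xm, "dropped") <- NULL
  list(data = xm, complete = x, model = design$model,
       dropped = if (is.null(dropped)) 0L else dropped)
}
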