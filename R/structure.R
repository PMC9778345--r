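# Expert-knowledge constraints: structural zeros of the precision matrix
# (known conditional independencies) imposed on the covariance update.

# normalize a structure specification to a 2-column matrix of unordered
# 1-based pairs; accepts a 2-column matrix or a list of length-2 vectors
normalize_structure <- function(structure, p) {
  if (is.null(structure)) return(matrix(integer(0), 0, 2))
  if (is.list(structure)) structure <- do.call(rbind, lapply(structure, as.integer))
  structure <- as.matrix(structure)
  if (ncol(structure) != 2L) stop("'structure' must be pairs of column indices")
  storage.mode(structure) <- "integer"
  if (any(structure < 1L) || any(structure > p))
    stop("structure indices must lie in 1..p")
  if (any(structure[, 1L] == structure[, 2L]))
    stop("structure pairs must involve two distinct columns")
  pairs <- cbind(pmin(structure[, 1L], structure[, 2L]),
                 pmax(structure[, 1L], structure[, 2L]))
  unique(pairs)
}

#' Covariance update under precision-matrix zero constraints
#'
#' Maximizes the latent Gaussian likelihood `-log|Sigma| - tr(Sigma^{-1} S)`
#' subject to `(Sigma^{-1})[j,k] = 0` for every constrained pair, after
#' normalizing `S` to the correlation scale. Uses the known-structure
#' iterative conditional-regression algorithm: cycle over columns, solving
#' the reduced linear system over the unconstrained entries, until the free
#' entries of the estimate match the normalized statistic. The free
#' off-diagonal entries of the solution equal those of the normalized `S`;
#' the constrained entries are filled in so the implied precision is zero
#' there. The diagonal is exactly 1.
#'
#' @param S p x p sufficient statistic (positive definite after
#'   correlation normalization).
#' @param structure pairs constrained to zero in the precision matrix: a
#'   2-column matrix or list of length-2 vectors of 1-based column indices.
#' @param tol convergence tolerance on entry changes.
#' @param maxit cycle cap; non-convergence warns and returns the iterate.
#' @return a unit-diagonal correlation matrix whose precision is zero on
#'   the constrained pairs.
#' @export
constrained_sigma_update <- function(S, structure, tol = 1e-8, maxit = 500L) {
  Sc <- sigma_update(S)
  p <- nrow(Sc)
  pairs <- normalize_structure(structure, p)
  if (nrow(pairs) == 0L) return(Sc)
  free <- matrix(TRUE, p, p); diag(free) <- FALSE
  free[pairs] <- FALSE
  free[pairs[, 2:1, drop = FALSE]] <- FALSE
  W <- Sc
  done <- FALSE
  for (it in seq_len(maxit)) {
    Wold <- W
    for (j in seq_len(p)) {
      mj <- setdiff(seq_len(p), j)
      nb <- which(free[mj, j])            # positions (within mj) of free entries
      w12 <- numeric(p - 1L)
      if (length(nb)) {
        W11 <- W[mj, mj, drop = FALSE]
        beta <- numeric(p - 1L)
        beta[nb] <- solve(W11[nb, nb, drop = FALSE], Sc[mj, j][nb])
        w12 <- drop(W11 %*% beta)
      }
      W[mj, j] <- w12
      W[j, mj] <- w12
    }
    if (max(abs(W - Wold)) < tol) { done <- TRUE; break }
  }
  if (!done)
    warning(sprintf("constrained covariance update did not converge in %d cycles; max residual %.2e",
                    maxit, max(abs(W - Wold))))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  W
}

#' Check that a correlation matrix respects a precision structure
#'
#' @param sigma correlation matrix.
#' @param structure constrained pairs (see [constrained_sigma_update()]).
#' @param tol absolute tolerance on the precision entries.
#' @return `TRUE` iff all constrained precision entries are below `tol`
#'   in magnitude.
#' @export
verify_structure <- function(sigma, structure, tol = 1e-6) {
  pairs <- normalize_structure(structure, nrow(sigma))
  if (nrow(pairs) == 0L) return(TRUE)
  K <- solve(sigma)
  all(abs(K[pairs]) < tol)
}
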