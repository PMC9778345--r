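#' Read and write numeric tables with missing cells
#'
#' `read_missing_csv` reads a rectangular numeric CSV with a header row;
#' empty cells and any of the `missing` tokens become `NA`. Non-numeric
#' observed cells raise an error naming the column. `write_missing_csv`
#' writes the complement: missing cells become the first `missing` token
#' (the empty string by default), so a write-read round trip preserves
#' values and mask.
#'
#' @param path file path.
#' @param missing character vector of tokens treated as missing.
#' @return `read_missing_csv`: a numeric matrix with `NA` at missing
#'   cells and the header as column names.
#' @export
read_missing_csv <- function(path, missing = c("", "NA", "NaN")) {
  df <- utils::read.csv(path, header = TRUE, na.strings = missing,
                        check.names = FALSE, colClasses = NA)
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- suppressWarnings(as.numeric(as.character(df[[j]])))
      if (any(is.na(bad) & !is.na(df[[j]])))
        stop("non-numeric observed cell in column '", names(df)[j], "'")
      df[[j]] <- bad
    }
  }
  as.matrix(df)
}

#' @rdname read_missing_csv
#' @param x numeric matrix with `NA` at missing cells.
#' @export
write_missing_csv <- function(x, path, missing = "") {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   na = missing[1L], quote = FALSE)
}

#' Write a plain-text report of a fitted model
#'
#' Serializes the correlation matrix at full precision, the marginal
#' family and parameters per column, and the iteration log.
#'
#' @param fit a fitted `"gcm"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gcm_report <- function(fit, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("method: %s", fit$method)
  w("seed: %s", fit$seed)
  w("iterations: %d", fit$iterations)
  w("converged: %s", fit$converged)
  w("sigma:")
  apply(fit$model$sigma, 1, function(r)
    w("  %s", paste(format(r, digits = 17), collapse = " ")))
  w("marginals:")
  for (j in seq_along(fit$model$marginals)) {
    m <- fit$model$marginals[[j]]
    if (inherits(m, "mixture_marginal"))
      w("  %s: family=mixture sigma=%s means=%s", fit$model$names[j],
        format(m$sigma, digits = 17),
        paste(format(m$means, digits = 17), collapse = ","))
    else if (inherits(m, "chisq_marginal"))
      w("  %s: family=chi2 df=%g", fit$model$names[j], m$df)
    else if (inherits(m, "empirical_marginal"))
      w("  %s: family=ecdf n=%d", fit$model$names[j], m$n)
    else
      w("  %s: family=normal mean=%g sd=%g", fit$model$names[j], m$mean, m$sd)
  }
  w("trajectory:")
  w("  iter M sigma_change objective")
  for (i in seq_len(nrow(fit$trajectory)))
    w("  %d %d %s %s", fit$trajectory$iter[i], fit$trajectory$M[i],
      format(fit$trajectory$sigma_change[i], digits = 10),
      format(fit$trajectory$objective[i], digits = 10))
  invisible(path)
}
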