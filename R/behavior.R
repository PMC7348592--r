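# Brain-behavior association: partial correlation controlling for
# demographic covariates.

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the OLS residuals of `x` and `y` on an
#' intercept plus the covariates (age, gender, education), with a t-based
#' p-value on `df = n - 2 - k` degrees of freedom.
#'
#' @param x,y per-subject values.
#' @param covariates a [covariate_table()] aligned with `x`/`y`; `NULL`
#'   reduces to the plain Pearson correlation.
#' @return object of class `partial_correlation`: `r_partial`, `df`,
#'   `p_value`, `n`, `covariate_names`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else 3L
  if (n <= k + 3) stop("too few subjects for a partial correlation")
  if (is.null(covariates)) {
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    rx <- residualize(x, covariates)
    ry <- residualize(y, covariates)
  }
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero-variance residual: correlation undefined")
  r <- cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  structure(list(r_partial = r, df = df, p_value = p, n = n,
                 covariate_names = if (k) c("age", "gender", "education")
                 else character(0)),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("Partial correlation: r = %.3f, df = %d, p = %.4g (n = %d%s)\n",
              x$r_partial, x$df, x$p_value, x$n,
              if (length(x$covariate_names))
                paste0("; controlling ",
                       paste(x$covariate_names, collapse = ", ")) else ""))
  invisible(x)
}
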