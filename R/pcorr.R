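#' Partial Pearson correlations adjusted for all other variables
#'
#' Computes, for every pair of columns, the partial Pearson correlation given
#' all remaining columns, via the standardized inverse of the correlation
#' matrix: `rho_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`. This is
#' algebraically identical to the per-pair residual-regression definition but
#' requires a single matrix inversion. P-values come from the t transform
#' with `df = n - p` degrees of freedom. When `n <= p` (or the correlation
#' matrix is singular) the exact mode is unavailable; `method = "ridge"` adds
#' `lambda` to the diagonal of the correlation matrix before inversion and is
#' flagged in the result. Binary 0/1 features may be included as numeric.
#'
#' @param X Numeric n x p matrix with non-constant, complete columns.
#' @param method `"exact"` (default) or `"ridge"`.
#' @param lambda Ridge regularization added to the correlation diagonal.
#' @return An object of class `pcorr`: list with `rho` and `p` (p x p
#'   symmetric matrices, unit/NA diagonal), `df`, `method`, `lambda`.
#' @export
partial_corr_matrix <- function(X, method = c("exact", "ridge"), lambda = 0.1) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X)) domain_error("X must be complete (impute upstream)")
  if (any(apply(X, 2, stats::sd) == 0)) domain_error("constant column in X")
  R <- stats::cor(X)
  if (method == "exact") {
    if (n <= p)
      domain_error("exact mode needs n > p (n = %d, p = %d); use method = 'ridge'", n, p)
    Omega <- tryCatch(solve(R), error = function(e)
      domain_error("singular correlation matrix; use method = 'ridge'"))
  } else {
    Omega <- solve(R + diag(lambda, p))
  }
  d <- sqrt(diag(Omega))
  rho <- -Omega / outer(d, d)
  diag(rho) <- 1
  df <- n - p
  pmat <- matrix(NA_real_, p, p, dimnames = dimnames(rho))
  if (df > 0) {
    tstat <- rho * sqrt(df / pmax(1 - rho^2, .Machine$double.eps))
    pmat <- 2 * stats::pt(-abs(tstat), df)
  }
  diag(pmat) <- NA_real_
  structure(list(rho = rho, p = pmat, df = df, n = n, method = method,
                 lambda = if (method == "ridge") lambda else NA_real_),
            class = "pcorr")
}

#' @export
print.pcorr <- function(x, ...) {
  cat(sprintf("pcorr: %d variables, n = %d, df = %d, method = %s\n",
              ncol(x$rho), x$n, x$df, x$method))
  invisible(x)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` *and each covariate column*, residualizes the
#' `x`/`y` ranks on the covariate ranks by least squares, and computes the
#' Pearson correlation of the residuals (the convention of the ppcor-style
#' Spearman partial correlation; ranking the covariates makes the adjustment
#' insensitive to monotone covariate transformations). P-value from the t
#' transform with `df = n - k - 2` (k covariates). With no covariates this
#' reduces to the plain Spearman correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix or data frame of covariates.
#' @return List with `rho`, `p`, `n`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(Z)) keep <- keep & stats::complete.cases(Z)
  x <- x[keep]; y <- y[keep]
  if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= k + 2) domain_error("need n > #covariates + 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) domain_error("constant input")
  rx <- rank(x); ry <- rank(y)
  if (!is.null(Z)) {
    D <- cbind(1, apply(Z, 2, rank))
    rx <- stats::lm.fit(D, rx)$residuals
    ry <- stats::lm.fit(D, ry)$residuals
  }
  rho <- stats::cor(rx, ry)
  df <- n - k - 2
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}
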