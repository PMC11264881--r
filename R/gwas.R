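#' Additive per-SNP association scan
#'
#' For each SNP, ordinary least squares of the metabolite on the 0/1/2 dosage
#' plus covariates, reporting the per-allele effect, its standard error, the
#' two-sided Wald p-value, minor-allele frequency and sample size. Computed by
#' residualizing both the outcome and the dosage matrix on the covariates
#' (Frisch-Waugh), which equals the per-SNP joint regression exactly.
#' Monomorphic SNPs are emitted with `NA` estimates and flagged.
#'
#' @param genotypes n x m numeric dosage matrix (0/1/2), column names SNP ids.
#' @param y Metabolite vector (non-constant).
#' @param covariates Optional numeric covariate matrix (no intercept column).
#' @return Data frame with columns `snp`, `beta`, `se`, `p`, `maf`, `n`,
#'   `flagged`.
#' @export
gwas_scan <- function(genotypes, y, covariates = NULL) {
  G <- as.matrix(genotypes)
  n <- nrow(G)
  if (length(y) != n) domain_error("y must have one value per genotyped sample")
  if (stats::sd(y) == 0) domain_error("constant metabolite vector")
  D <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates))
  if (n <= ncol(D) + 1) domain_error("need n > #covariates + 2")
  qrD <- qr(D)
  ry <- qr.resid(qrD, y)
  RG <- qr.resid(qrD, G)
  Sxx <- colSums(RG^2)
  mono <- Sxx < 1e-12
  beta <- colSums(RG * ry) / ifelse(mono, NA_real_, Sxx)
  df <- n - ncol(D) - 1L
  rss <- sum(ry^2) - beta^2 * Sxx
  sigma2 <- rss / df
  se <- sqrt(sigma2 / Sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  af <- colMeans(G) / 2
  out <- data.frame(
    snp = colnames(G) %||% sprintf("snp%05d", seq_len(ncol(G))),
    beta = beta, se = se, p = p, maf = pmin(af, 1 - af), n = n,
    flagged = mono, stringsAsFactors = FALSE
  )
  out$beta[mono] <- NA_real_; out$se[mono] <- NA_real_; out$p[mono] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Genomic-control inflation factor
#'
#' Median association chi-square divided by its null median (0.4549).
#'
#' @param p Vector of association p-values (NA dropped).
#' @return Lambda-GC.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) domain_error("no p-values")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Write a PLINK-style association table
#' @param rows Output of [gwas_scan()].
#' @param path Output path (tab-delimited, columns SNP BETA SE P MAF N).
#' @export
write_gwas_results <- function(rows, path) {
  out <- data.frame(SNP = rows$snp, BETA = rows$beta, SE = rows$se,
                    P = rows$p, MAF = rows$maf, N = rows$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' LASSO phenome-wide determinant scan
#'
#' L1-penalized least squares (coordinate descent via glmnet) of a metabolite
#' on a mixed predictor table; the penalty is chosen by k-fold
#' cross-validated prediction error with the 1-SE rule. Reports the nonzero
#' coefficients ranked by absolute magnitude and the cross-validated R².
#'
#' @param y Metabolite vector.
#' @param predictors n x k numeric matrix (k >= 2); factors must be coded
#'   numerically upstream.
#' @param folds Cross-validation folds (default 10, >= 2).
#' @param seed Optional seed for the fold assignment.
#' @param standardize Standardize predictors inside the solver (default TRUE).
#' @param lambda Optional user lambda path for the cross-validation.
#' @param fixed_lambda If given, skip cross-validation and solve at exactly
#'   this penalty (tight convergence threshold); `cv_r2` is then `NA`.
#' @param intercept Fit an intercept (default TRUE).
#' @return List with `coefficients` (named, nonzero, sorted by |coef|),
#'   `cv_r2`, `lambda`, `ranking` (predictor names in rank order) and the
#'   underlying glmnet fit.
#' @export
lasso_phewas <- function(y, predictors, folds = 10L, seed = NULL,
                         standardize = TRUE, lambda = NULL,
                         fixed_lambda = NULL, intercept = TRUE) {
  X <- as.matrix(predictors)
  if (ncol(X) < 2) config_error("need k >= 2 predictors")
  if (folds < 2) config_error("folds must be >= 2")
  if (nrow(X) < folds) config_error("n < folds")
  if (!is.null(fixed_lambda)) {
    lam_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
    path <- sort(unique(c(fixed_lambda, lam_max * c(2, 1, 0.5, 0.1))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, standardize = standardize,
                          intercept = intercept, lambda = path,
                          thresh = 1e-14)
    cf <- as.matrix(stats::coef(fit, s = fixed_lambda))[-1, 1]
    nz <- cf[cf != 0]
    nz <- nz[order(-abs(nz))]
    return(list(coefficients = nz, cv_r2 = NA_real_, lambda = fixed_lambda,
                ranking = names(nz), fit = fit))
  }
  if (!is.null(seed)) set.seed(seed)
  cv <- glmnet::cv.glmnet(X, y, nfolds = folds, standardize = standardize,
                          lambda = lambda)
  s <- cv$lambda.1se
  cf <- as.matrix(stats::coef(cv, s = s))[-1, 1]
  nz <- cf[cf != 0]
  nz <- nz[order(-abs(nz))]
  i <- which(cv$lambda == s)
  cv_r2 <- 1 - cv$cvm[i] / stats::var(y)
  list(coefficients = nz, cv_r2 = cv_r2, lambda = s,
       ranking = names(nz), fit = cv)
}
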