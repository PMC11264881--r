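#' Model specification for the metabolome-wide association scan
#'
#' `model1` (primary) adjusts for the matching factors: gestational age, age
#' at sampling, season of birth (categorical, winter reference) and birth
#' year. `model2` additionally adjusts for family history of psychiatric
#' disorders, the polygenic score and six genetic principal components.
#' `custom` takes an explicit covariate list.
#'
#' @param model `"model1"`, `"model2"` or `"custom"`.
#' @param outcome `"case_status"` (logistic), `"family_history"` (logistic)
#'   or `"prs"` (linear).
#' @param covariates For `model = "custom"`, character vector of column names
#'   in the sample records.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = c("model1", "model2", "custom"),
                       outcome = c("case_status", "family_history", "prs"),
                       covariates = NULL) {
  model <- match.arg(model)
  outcome <- match.arg(outcome)
  covariates <- switch(model,
    model1 = c("gestational_age", "age_at_sampling", "season", "birth_year"),
    model2 = c("gestational_age", "age_at_sampling", "season", "birth_year",
               "family_history", "prs", paste0("pc", 1:6)),
    custom = covariates %||% character(0)
  )
  structure(list(model = model, outcome = outcome, covariates = covariates),
            class = "model_spec")
}

# Design matrix (no intercept column; added by the fitters). Season enters as
# three dummies with winter as reference.
covariate_matrix <- function(samples, covariates) {
  if (!length(covariates)) return(NULL)
  missing_cols <- setdiff(covariates, names(samples))
  if (length(missing_cols))
    config_error("sample records lack covariate(s): %s",
                 paste(missing_cols, collapse = ", "))
  cols <- list()
  for (cv in covariates) {
    v <- samples[[cv]]
    if (cv == "season") {
      v <- factor(v, levels = c("winter", "spring", "summer", "autumn"))
      for (lev in levels(v)[-1]) cols[[paste0("season_", lev)]] <- as.numeric(v == lev)
    } else cols[[cv]] <- as.numeric(v)
  }
  do.call(cbind, cols)
}

outcome_vector <- function(samples, outcome) {
  switch(outcome,
    case_status = as.numeric(samples$group == "case"),
    family_history = as.numeric(samples$family_history),
    prs = as.numeric(samples$prs)
  )
}

# Maximum-likelihood logistic fit via IRLS (glm.fit); returns coefficients,
# standard errors and a separation/convergence flag.
logistic_fit <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  cf <- fit$coefficients
  ok <- fit$converged && all(is.finite(cf)) && max(abs(cf[-1]), 0) < 15
  se <- rep(NA_real_, length(cf))
  if (all(is.finite(cf))) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(cv)) ok <- FALSE else se <- sqrt(diag(cv))
  }
  ok <- ok && all(is.finite(se)) && max(se) < 10
  list(coef = cf, se = se, converged = ok)
}

# Firth-type penalized-likelihood logistic regression (Jeffreys prior),
# used as the fallback under complete or quasi-complete separation.
firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((XW %*% inv) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  list(coef = beta, se = sqrt(diag(inv)), converged = TRUE)
}

assoc_row <- function(feature_id, mode, estimate, ci_low, ci_high, p,
                      model_id, n_used, flagged = FALSE) {
  data.frame(feature_id = feature_id, mode = mode, estimate = estimate,
             ci_low = ci_low, ci_high = ci_high, p = p, q = NA_real_,
             model_id = model_id, n_used = n_used, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Single-feature association fit
#'
#' Covariate-adjusted maximum-likelihood logistic regression of a binary
#' outcome on one metabolite feature. For `continuous_per_sd` the feature is
#' expected standardized, so `exp(coef)` is the odds ratio per SD increment;
#' for `binary_presence` the 0/1 presence indicator is used; `quartile` emits
#' one odds ratio per quartile versus quartile 1 (reference, OR fixed at 1);
#' `linear` fits ordinary least squares and reports beta. Confidence bounds
#' and p-values are Wald. Complete or quasi-complete separation triggers a
#' Firth-type penalized-likelihood refit, flagged in the output.
#'
#' @param y Outcome vector (0/1 for logistic modes, numeric for `linear`).
#' @param x Feature vector (standardized values, presence indicator, or
#'   quartile labels 1-4 for `mode = "quartile"`).
#' @param covariates Optional numeric covariate matrix (no intercept).
#' @param mode Feature modeling mode.
#' @param feature_id,model_id Labels for the result row.
#' @return A one-row (or, for quartiles, four-row) `assoc_results` data frame.
#' @export
fit_feature_assoc <- function(y, x, covariates = NULL,
                              mode = c("continuous_per_sd", "binary_presence",
                                       "quartile", "linear"),
                              feature_id = "feature", model_id = "custom") {
  mode <- match.arg(mode)
  n <- length(y)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]; x <- x[keep]
  Z <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  n_used <- length(y)

  if (mode == "linear") {
    X <- cbind(intercept = 1, x = as.numeric(x), Z)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- n_used - ncol(X)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(diag(XtXinv) * rss / df)[2]
    b <- fit$coefficients[2]
    tval <- b / se
    p <- 2 * stats::pt(-abs(tval), df)
    return(assoc_row(feature_id, mode, b, b - 1.96 * se, b + 1.96 * se, p,
                     model_id, n_used))
  }

  if (length(unique(y)) < 2) domain_error("outcome has a single class")
  if (min(table(y)) < 10)
    domain_error("need >= 10 observations per outcome class, got %d", min(table(y)))

  if (mode == "quartile") {
    q <- factor(as.integer(x), levels = 1:4)
    D <- stats::model.matrix(~q)[, -1, drop = FALSE]
    X <- cbind(intercept = 1, D, Z)
    fit <- logistic_fit(X, y)
    flagged <- !fit$converged
    if (flagged) fit <- firth_logistic(X, y)
    rows <- assoc_row(feature_id, "quartile", 1, 1, 1, NA_real_, model_id,
                      n_used, flagged)
    rows$quartile <- 1L
    for (k in 2:4) {
      j <- which(colnames(X) == paste0("q", k))
      b <- fit$coef[j]; se <- fit$se[j]
      r <- assoc_row(feature_id, "quartile", exp(b), exp(b - 1.96 * se),
                     exp(b + 1.96 * se), 2 * stats::pnorm(-abs(b / se)),
                     model_id, n_used, flagged)
      r$quartile <- k
      rows <- rbind(rows, r)
    }
    class(rows) <- c("assoc_results", "data.frame")
    return(rows)
  }

  X <- cbind(intercept = 1, x = as.numeric(x), Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) domain_error("collinear covariates (rank-deficient design)")
  fit <- logistic_fit(X, y)
  flagged <- !fit$converged
  if (flagged) fit <- firth_logistic(X, y)
  b <- fit$coef[2]; se <- fit$se[2]
  out <- assoc_row(feature_id, mode, exp(b), exp(b - 1.96 * se),
                   exp(b + 1.96 * se), 2 * stats::pnorm(-abs(b / se)),
                   model_id, n_used, flagged)
  class(out) <- c("assoc_results", "data.frame")
  out
}

#' Metabolome-wide association scan
#'
#' Fits one covariate-adjusted regression per retained feature: continuous
#' features per standard deviation, binary features on the presence
#' indicator. Benjamini-Hochberg q-values are appended jointly across all
#' tested features. A feature whose fit fails contributes p = 1 (conservative)
#' and an `NA` estimate, and is logged.
#'
#' @param processed A `processed_features` object.
#' @param samples Sample records aligned to the processed rows by `sample_id`.
#' @param spec A [model_spec].
#' @return An `assoc_results` data frame, one row per feature, with `q`.
#' @export
run_mwas <- function(processed, samples, spec = model_spec("model1")) {
  stopifnot(inherits(processed, "processed_features"), inherits(spec, "model_spec"))
  ids <- rownames(processed$continuous) %||% rownames(processed$binary)
  idx <- match(ids, samples$sample_id)
  if (any(is.na(idx))) config_error("processed samples missing from sample records")
  samples <- samples[idx, ]
  y <- outcome_vector(samples, spec$outcome)
  Z <- covariate_matrix(samples, spec$covariates)
  linear <- spec$outcome == "prs"
  log_lines <- character(0)

  fit_block <- function(mat, mode) {
    if (is.null(mat)) return(NULL)
    rows <- lapply(colnames(mat), function(f) {
      tryCatch(
        fit_feature_assoc(y, mat[, f], Z,
                          mode = if (linear) "linear" else mode,
                          feature_id = f, model_id = spec$model),
        error = function(e) {
          log_lines <<- c(log_lines, sprintf("mwas: feature=%s failed (%s)",
                                             f, conditionMessage(e)))
          assoc_row(f, mode, NA_real_, NA_real_, NA_real_, 1, spec$model, 0, TRUE)
        })
    })
    do.call(rbind, rows)
  }

  res <- rbind(fit_block(processed$continuous, "continuous_per_sd"),
               fit_block(processed$binary, "binary_presence"))
  res$q <- bh_adjust(res$p)
  class(res) <- c("assoc_results", "data.frame")
  add_log(res, log_lines)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param pvals P-values in (0, 1].
#' @return Step-up adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) domain_error("bh_adjust needs at least one p-value")
  stats::p.adjust(pvals, method = "BH")
}

#' Age-of-diagnosis stratified analysis with interaction test
#'
#' Splits cases at an age-of-diagnosis threshold and fits the primary model
#' separately in each stratum (each stratum's cases versus *all* controls; the
#' controls are shared across strata and the output flags this). The
#' interaction p-value is a Wald test on the feature-by-early-stratum product
#' term in a stacked model over both strata (controls duplicated, consistent
#' with sharing).
#'
#' @param y Case indicator (0/1).
#' @param x Feature vector (standardized or presence-coded).
#' @param covariates Numeric covariate matrix.
#' @param age_at_diagnosis Years; `NA` for controls.
#' @param split Threshold in years (default 6; "early" is `< split`).
#' @return Data frame with `or_early`, `or_late`, their CIs and p-values, and
#'   `p_interaction`; `controls_shared` is always `TRUE`.
#' @export
stratified_interaction <- function(y, x, covariates = NULL, age_at_diagnosis,
                                   split = 6) {
  is_case <- y == 1
  early <- is_case & !is.na(age_at_diagnosis) & age_at_diagnosis < split
  late <- is_case & !is.na(age_at_diagnosis) & age_at_diagnosis >= split
  if (!any(early) || !any(late))
    domain_error("empty diagnosis-age stratum at split = %g", split)

  sub <- function(sel) {
    fit_feature_assoc(y[sel], x[sel],
                      if (is.null(covariates)) NULL
                      else covariates[sel, , drop = FALSE],
                      mode = "continuous_per_sd", feature_id = "feature",
                      model_id = "model1")
  }
  f_early <- sub(early | !is_case)
  f_late <- sub(late | !is_case)

  # stacked product-term model: both strata, controls entering twice
  sel_e <- which(early | !is_case)
  sel_l <- which(late | !is_case)
  idx <- c(sel_e, sel_l)
  s <- c(rep(1, length(sel_e)), rep(0, length(sel_l)))
  Z <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
  X <- cbind(intercept = 1, x = x[idx], s = s, xs = x[idx] * s, Z)
  keep <- stats::complete.cases(X)
  fit <- logistic_fit(X[keep, , drop = FALSE], y[idx][keep])
  if (!fit$converged) fit <- firth_logistic(X[keep, , drop = FALSE], y[idx][keep])
  j <- which(colnames(X) == "xs")
  z <- fit$coef[j] / fit$se[j]
  data.frame(
    or_early = f_early$estimate, ci_low_early = f_early$ci_low,
    ci_high_early = f_early$ci_high, p_early = f_early$p,
    or_late = f_late$estimate, ci_low_late = f_late$ci_low,
    ci_high_late = f_late$ci_high, p_late = f_late$p,
    p_interaction = 2 * stats::pnorm(-abs(z)),
    n_early_cases = sum(early), n_late_cases = sum(late),
    controls_shared = TRUE
  )
}

#' Rank-based (Mann-Whitney) AUC of a single marker
#'
#' @param marker Numeric marker values.
#' @param y Class labels (0/1); ties in the marker count one half.
#' @return AUC in `[0, 1]` for discriminating `y == 1`.
#' @export
auc_single <- function(marker, y) {
  keep <- !is.na(marker) & !is.na(y)
  marker <- marker[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) domain_error("both classes must be present")
  r <- rank(marker)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson chi-square test for a contingency table
#'
#' Without continuity correction, as used for categorical cohort-table
#' comparisons.
#'
#' @param counts Matrix of counts (r x c).
#' @return List with `statistic`, `df`, `p` (class `test_result`).
#' @export
contingency_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    domain_error("zero marginal in contingency table")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected <= 0)) domain_error("non-positive expected count")
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value), class = "test_result")
}

#' Two-sample t-test (pooled variance)
#'
#' Equal-variance two-sided t-test, the convention used for continuous
#' cohort-table comparisons; Welch's form is available via `var_equal`.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param var_equal Pooled (default `TRUE`) or Welch.
#' @return List with `statistic`, `df`, `p` (class `test_result`).
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    domain_error("each group needs >= 2 values")
  if (stats::var(a) + stats::var(b) == 0)
    domain_error("zero pooled variance")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("statistic = %.4f, df = %.4g, p = %.4g\n", x$statistic, x$df, x$p))
  invisible(x)
}
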