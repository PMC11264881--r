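#' Relative standard deviation of repeated QC injections
#'
#' @param values Positive intensities from repeated injections (>= 2).
#' @return RSD in percent: `100 * sd(values) / mean(values)`.
#' @export
qc_rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) domain_error("qc_rsd needs >= 2 values")
  if (any(values <= 0)) domain_error("qc_rsd requires strictly positive values")
  100 * stats::sd(values) / mean(values)
}

#' Fit a LOESS drift curve to QC intensities
#'
#' Locally weighted (tricube) regression of QC intensity on injection order,
#' the curve used for QC-based robust LOESS signal correction (QC-RLSC).
#' The span is the fraction of QC points entering each local fit; the
#' reference value is the median of the QC intensities. Evaluation outside the
#' observed QC order range is clamped to the nearest fitted value, so the
#' correction never extrapolates.
#'
#' @param qc_orders Integer injection orders of the QC points (>= 4).
#' @param qc_values Positive QC intensities.
#' @param span LOESS span (alpha), default 2/3.
#' @param degree Local polynomial degree, 1 (default) or 2.
#' @return An object of class `drift_curve` with elements `fit`, `reference`,
#'   `range` and `positive`, evaluable with [predict_drift()].
#' @export
fit_drift_curve <- function(qc_orders, qc_values, span = 2 / 3, degree = 1L) {
  keep <- !is.na(qc_values) & !is.na(qc_orders)
  qc_orders <- qc_orders[keep]; qc_values <- qc_values[keep]
  if (length(qc_orders) < 4)
    nm_error("neometab_insufficient_qc", "need >= 4 QC points, got %d", length(qc_orders))
  if (any(qc_values <= 0)) domain_error("QC intensities must be strictly positive")
  if (!degree %in% c(1L, 2L)) config_error("degree must be 1 or 2")
  if (span <= 0 || span > 1) config_error("span must lie in (0, 1]")
  # few QC points per plate are the normal regime; loess then warns about
  # pseudoinverse use, which is expected and harmless
  fit <- suppressWarnings(
    stats::loess(y ~ x, data = data.frame(x = qc_orders, y = qc_values),
                 span = span, degree = degree, family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  rng <- range(qc_orders)
  grid <- seq(rng[1], rng[2], length.out = max(50L, diff(rng) + 1L))
  pos <- all(suppressWarnings(stats::predict(fit, data.frame(x = grid))) > 0)
  structure(list(fit = fit, reference = stats::median(qc_values),
                 range = rng, span = span, degree = degree, positive = pos),
            class = "drift_curve")
}

#' Evaluate a drift curve at injection orders
#' @param curve A `drift_curve` from [fit_drift_curve()].
#' @param orders Injection orders; clamped to the fitted QC order range.
#' @return Fitted intensities.
#' @export
predict_drift <- function(curve, orders) {
  x <- pmin(curve$range[2], pmax(curve$range[1], orders))
  as.numeric(suppressWarnings(stats::predict(curve$fit, data.frame(x = x))))
}

#' Fit per-plate (or global) drift curves for every feature
#'
#' @param table A [feature_table] containing QC rows.
#' @param span,degree Passed to [fit_drift_curve()].
#' @param qc_type QC rows used for fitting (default the plate-specific pools).
#' @param per_plate Fit one curve per (plate, feature) (default) or one global
#'   curve per feature across plates.
#' @return An object of class `drift_model`: a list of curves indexed by
#'   `plate` and `feature`, with a log of features skipped for insufficient QC.
#' @export
fit_drift_model <- function(table, span = 2 / 3, degree = 1L,
                            qc_type = "plate_pool", per_plate = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  qc <- table$qc_flag %in% qc_type
  if (!any(qc)) domain_error("no QC rows of type %s", paste(qc_type, collapse = "/"))
  plates <- if (per_plate) unique(table$plate) else "__global__"
  curves <- list(); log_lines <- character(0)
  for (pl in plates) {
    sel <- qc & (if (per_plate) table$plate == pl else TRUE)
    ord <- table$injection_order[sel]
    curves[[pl]] <- lapply(feature_ids(table), function(f) {
      vals <- table$intensities[sel, f]
      tryCatch(fit_drift_curve(ord, vals, span, degree),
               neometab_insufficient_qc = function(e) {
                 log_lines <<- c(log_lines, sprintf(
                   "drift: plate=%s feature=%s skipped (%s)", pl, f, conditionMessage(e)))
                 NULL
               })
    })
    names(curves[[pl]]) <- feature_ids(table)
  }
  # study-wide per-feature QC median: dividing by the plate's curve and
  # multiplying by this reference corrects drift and plate level together
  reference <- apply(table$intensities[qc, , drop = FALSE], 2,
                     stats::median, na.rm = TRUE)
  structure(list(curves = curves, reference = reference,
                 per_plate = per_plate, span = span, degree = degree),
            class = "drift_model", log = log_lines)
}

#' Apply QC-based drift correction to a feature table
#'
#' Each intensity is corrected as `raw * reference / f(order)` where `f` is
#' the plate- and feature-specific drift curve and `reference` the study-wide
#' median QC intensity of the feature (so dividing by the plate's own curve
#' and multiplying back the common reference removes both drift and the
#' plate's overall level shift). Features without a fitted curve (insufficient QC)
#' or whose curve is not strictly positive over the plate's order range are
#' passed through unchanged and logged. Missing cells stay missing; QC rows
#' are corrected identically to analytical rows.
#'
#' @param table A [feature_table].
#' @param model A `drift_model` from [fit_drift_model()].
#' @return The corrected [feature_table]; skipped features are listed in
#'   [processing_log()].
#' @export
apply_drift_correction <- function(table, model) {
  stopifnot(inherits(table, "feature_table"), inherits(model, "drift_model"))
  mat <- table$intensities
  log_lines <- character(0)
  plates <- if (model$per_plate) unique(table$plate) else "__global__"
  for (pl in plates) {
    rows <- if (model$per_plate) which(table$plate == pl)
            else seq_len(nrow(mat))
    ord <- table$injection_order[rows]
    plate_curves <- model$curves[[pl]]
    if (is.null(plate_curves)) {
      log_lines <- c(log_lines, sprintf("drift: plate=%s has no fitted curves", pl))
      next
    }
    for (f in colnames(mat)) {
      curve <- plate_curves[[f]]
      if (is.null(curve)) next  # already logged at fit time
      if (!curve$positive) {
        log_lines <- c(log_lines, sprintf(
          "drift: plate=%s feature=%s skipped (non-positive fitted curve)", pl, f))
        next
      }
      fhat <- predict_drift(curve, ord)
      ref <- model$reference[[f]] %||% curve$reference
      if (is.na(ref)) ref <- curve$reference
      mat[rows, f] <- mat[rows, f] * ref / fhat
    }
  }
  out <- feature_table(mat, table$plate, table$injection_order, table$qc_flag)
  add_log(out, c(processing_log(model), log_lines))
}

#' Per-plate median batch correction
#'
#' For each feature, log intensities are shifted per plate so that every
#' plate's median equals the grand median over analytical samples (a simple,
#' documented batch-correction stage). Missingness is unchanged. Plates in
#' which a feature is entirely missing are skipped and logged.
#'
#' @param table A [feature_table].
#' @param method `"plate_median"` or `"none"` (identity).
#' @return The corrected [feature_table].
#' @export
correct_batch <- function(table, method = c("plate_median", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "feature_table"))
  if (method == "none") return(table)
  mat <- table$intensities
  analytical <- table$qc_flag == "analytical"
  log_lines <- character(0)
  for (f in colnames(mat)) {
    v <- mat[, f]
    grand <- stats::median(log(v[analytical]), na.rm = TRUE)
    if (is.na(grand)) {
      log_lines <- c(log_lines, sprintf("batch: feature=%s all missing, skipped", f))
      next
    }
    for (pl in unique(table$plate)) {
      in_plate <- table$plate == pl
      med <- stats::median(log(v[in_plate & analytical]), na.rm = TRUE)
      if (is.na(med)) {
        log_lines <- c(log_lines, sprintf(
          "batch: plate=%s feature=%s all missing, skipped", pl, f))
        next
      }
      v[in_plate] <- exp(log(v[in_plate]) + grand - med)
    }
    mat[, f] <- v
  }
  out <- feature_table(mat, table$plate, table$injection_order, table$qc_flag)
  add_log(out, log_lines)
}

#' QC repeatability report
#'
#' Per-feature RSD of a chosen QC sample type before/after a correction.
#'
#' @param table A [feature_table].
#' @param qc_type QC rows to evaluate.
#' @param per_plate If `TRUE`, compute RSD within each plate and average
#'   across plates; otherwise pool all QC injections.
#' @return Data frame with `feature_id`, `rsd` (percent) and `n_qc`.
#' @export
qc_report <- function(table, qc_type = "plate_pool", per_plate = FALSE) {
  qc <- table$qc_flag %in% qc_type
  if (sum(qc) < 3) domain_error("need >= 3 QC rows for a QC report")
  mat <- table$intensities[qc, , drop = FALSE]
  plates <- table$plate[qc]
  rsd <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    if (per_plate) {
      per <- vapply(unique(plates), function(pl) {
        vv <- v[plates == pl]
        if (sum(!is.na(vv) & vv > 0) >= 2) qc_rsd(vv[vv > 0]) else NA_real_
      }, numeric(1))
      mean(per, na.rm = TRUE)
    } else if (sum(!is.na(v) & v > 0) >= 2) qc_rsd(v[!is.na(v) & v > 0])
    else NA_real_
  }, numeric(1))
  data.frame(feature_id = colnames(mat), rsd = rsd,
             n_qc = colSums(!is.na(mat)), stringsAsFactors = FALSE)
}

#' Impute missing values of continuous features
#'
#' Iterative per-feature regression-tree imputation: missing cells are
#' initialized at half the feature minimum (a standard detection-limit
#' surrogate), then each feature with missing values is regressed on the most
#' correlated other features with a regression tree and its missing entries
#' replaced by predictions. Features with too few observed values fall back to
#' half-minimum. Operates on log intensities internally.
#'
#' @param mat Numeric samples x features intensity matrix with `NA` missing.
#' @param max_iter Imputation sweeps (default 2).
#' @param n_predictors Maximum number of predictor features per tree.
#' @param min_obs Minimum observed values to fit a tree.
#' @return The completed matrix (strictly positive).
#' @export
impute_halfmin_tree <- function(mat, max_iter = 2L, n_predictors = 15L,
                                min_obs = 20L) {
  lg <- log(mat)
  miss <- is.na(lg)
  if (!any(miss)) return(mat)
  halfmin <- apply(lg, 2, function(v) min(v, na.rm = TRUE)) - log(2)
  halfmin[!is.finite(halfmin)] <- 0
  filled <- lg
  for (j in which(colSums(miss) > 0)) filled[miss[, j], j] <- halfmin[j]
  target_cols <- which(colSums(miss) > 0 & colSums(!miss) >= min_obs)
  if (length(target_cols) && ncol(lg) > 1) {
    for (iter in seq_len(max_iter)) {
      cmat <- suppressWarnings(stats::cor(filled))
      diag(cmat) <- 0
      for (j in target_cols) {
        pred <- order(abs(cmat[, j]), decreasing = TRUE)
        pred <- setdiff(pred, j)[seq_len(min(n_predictors, ncol(lg) - 1))]
        df <- data.frame(y = filled[, j], filled[, pred, drop = FALSE])
        obs <- !miss[, j]
        fit <- rpart::rpart(y ~ ., data = df[obs, , drop = FALSE],
                            method = "anova",
                            control = rpart::rpart.control(cp = 0.01, minsplit = 10))
        filled[miss[, j], j] <- stats::predict(fit, df[miss[, j], , drop = FALSE])
      }
    }
  }
  exp(filled)
}
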