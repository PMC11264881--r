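#' Per-feature presence fraction
#'
#' Fraction of analytical samples in which each feature was detected
#' (non-missing). QC rows are excluded.
#'
#' @param table A [feature_table].
#' @return Named numeric vector in `[0, 1]`.
#' @export
presence_fraction <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  a <- analytical_samples(table)
  if (nrow(a$intensities) == 0) domain_error("no analytical samples")
  colMeans(!is.na(a$intensities))
}

#' Partition features by presence fraction
#'
#' Implements the missingness triage rule: features present in less than
#' `low` of the samples are dropped, features present in fewer than `high`
#' are treated as binary (present/absent), and the rest are continuous.
#' The boundaries follow the rule's strict wording: a fraction exactly at
#' `low` is binary, exactly at `high` is continuous.
#'
#' @param fractions Presence fractions in `[0, 1]`.
#' @param low,high Stratum thresholds, defaults 0.25 and 0.75.
#' @return Character vector of labels `"dropped"`, `"binary"`, `"continuous"`.
#' @export
partition_features <- function(fractions, low = 0.25, high = 0.75) {
  if (low <= 0 || high <= low || high > 1)
    config_error("need 0 < low < high <= 1")
  if (any(fractions < 0 | fractions > 1)) domain_error("fractions must lie in [0, 1]")
  out <- ifelse(fractions < low, "dropped",
                ifelse(fractions < high, "binary", "continuous"))
  stats::setNames(out, names(fractions))
}

#' Presence indicator for a feature
#'
#' 1 where the value is non-missing (including measured zeros), 0 where
#' missing: missingness encodes "not detected", a zero is a measurement.
#'
#' @param values Numeric vector with `NA` for missing.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(values) as.integer(!is.na(values))

#' Rank-based quartile coding
#'
#' Assigns quartile labels 1-4 from average ranks over all non-missing values;
#' ties falling exactly on a quartile boundary go to the lower bin. Quartile 1
#' is the reference category in downstream regression.
#'
#' @param values Numeric vector (>= 8 non-missing, non-constant).
#' @return Integer vector of labels in `{1, 2, 3, 4}` (`NA` kept).
#' @export
quartile_bins <- function(values) {
  obs <- !is.na(values)
  n <- sum(obs)
  if (n < 8) domain_error("quartile_bins needs >= 8 non-missing values")
  v <- values[obs]
  if (max(v) == min(v)) domain_error("quartiles undefined for a constant vector")
  r <- rank(v, ties.method = "average")
  bins <- as.integer(cut(r, breaks = c(0, n / 4, n / 2, 3 * n / 4, n),
                         labels = FALSE, right = TRUE))
  out <- rep(NA_integer_, length(values))
  out[obs] <- bins
  out
}

#' Missingness-stratified feature processing
#'
#' Full triage of a feature table into the analysis blocks: features are
#' partitioned by presence fraction (see [partition_features()]); the binary
#' block is coded present/absent; the continuous block is imputed
#' ([impute_halfmin_tree()]), batch-corrected ([correct_batch()]),
#' log-transformed (natural log, default) and standardized to mean 0 / SD 1
#' over all analytical samples. Only analytical samples appear in the output
#' blocks.
#'
#' @param table A [feature_table] (drift-corrected upstream if desired).
#' @param low,high Partition thresholds.
#' @param log_transform Log-transform continuous intensities before
#'   standardization (default `TRUE`).
#' @param impute `"tree"` (default), `"half_min"`, or `"none"` (continuous
#'   features must then be complete).
#' @param batch_method Passed to [correct_batch()] for the continuous block.
#' @return An object of class `processed_features`: list with `continuous`
#'   (standardized matrix), `binary` (0/1 matrix), `strata` (data frame of
#'   per-feature labels and presence fractions), `dropped` (ids) and `meta`
#'   (the processing choices taken, for the run manifest).
#' @export
process_features <- function(table, low = 0.25, high = 0.75,
                             log_transform = TRUE,
                             impute = c("tree", "half_min", "none"),
                             batch_method = c("plate_median", "none")) {
  impute <- match.arg(impute)
  batch_method <- match.arg(batch_method)
  stopifnot(inherits(table, "feature_table"))

  frac <- presence_fraction(table)
  strata <- partition_features(frac, low, high)
  ana <- analytical_samples(table)

  cont_ids <- names(strata)[strata == "continuous"]
  bin_ids <- names(strata)[strata == "binary"]
  dropped <- names(strata)[strata == "dropped"]

  binary <- NULL
  if (length(bin_ids)) {
    binary <- apply(ana$intensities[, bin_ids, drop = FALSE], 2, binarize)
    rownames(binary) <- sample_ids(ana)
  }

  continuous <- NULL
  if (length(cont_ids)) {
    sub <- table[, cont_ids]
    mat <- sub$intensities
    if (anyNA(mat)) {
      if (impute == "none")
        domain_error("continuous block has missing values and impute='none'")
      mat <- if (impute == "tree") impute_halfmin_tree(mat)
             else {
               hm <- apply(mat, 2, function(v) min(v, na.rm = TRUE) / 2)
               for (j in seq_len(ncol(mat))) mat[is.na(mat[, j]), j] <- hm[j]
               mat
             }
    }
    sub <- feature_table(mat, sub$plate, sub$injection_order, sub$qc_flag)
    sub <- correct_batch(sub, batch_method)
    keep <- sub$qc_flag == "analytical"
    x <- sub$intensities[keep, , drop = FALSE]
    if (log_transform) x <- log(x)
    continuous <- scale(x)
    attr(continuous, "scaled:center") <- NULL
    attr(continuous, "scaled:scale") <- NULL
    continuous <- continuous[, , drop = FALSE]
  }

  structure(list(
    continuous = continuous, binary = binary,
    strata = data.frame(feature_id = names(strata), stratum = unname(strata),
                        presence_fraction = unname(frac), stringsAsFactors = FALSE),
    dropped = dropped,
    meta = list(low = low, high = high, log_transform = log_transform,
                impute = impute, batch_method = batch_method,
                standardization = "mean 0 / SD 1 over all analytical samples")
  ), class = "processed_features")
}

#' @export
print.processed_features <- function(x, ...) {
  tab <- table(factor(x$strata$stratum, c("continuous", "binary", "dropped")))
  cat(sprintf("processed_features: %d continuous, %d binary, %d dropped (of %d)\n",
              tab[1], tab[2], tab[3], nrow(x$strata)))
  invisible(x)
}
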