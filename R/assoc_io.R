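#' Association results table
#'
#' Association results are plain data frames with one row per tested feature
#' (or per quartile contrast) and columns `feature_id`, `mode`
#' (`continuous_per_sd`, `binary_presence`, `quartile`, `linear`), `estimate`
#' (odds ratio for logistic modes, beta for linear), `ci_low`, `ci_high`
#' (Wald 95% bounds on the same scale), `p`, `q` (BH-adjusted), `model_id`
#' and `n_used`.
#'
#' @param results Data frame of association results.
#' @param path Output path (tab-delimited).
#' @return Invisibly, `results`.
#' @export
write_assoc_results <- function(results, path) {
  cols <- c("feature_id", "mode", "estimate", "ci_low", "ci_high",
            "p", "q", "model_id", "n_used")
  if (is.null(results) || nrow(as.data.frame(results)) == 0L)
    format_error("refusing to write an empty association results table")
  results <- as.data.frame(results)
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols))
    format_error("results lack column(s): %s", paste(missing_cols, collapse = ", "))
  out <- results[, cols]
  for (nm in c("estimate", "ci_low", "ci_high", "p", "q"))
    out[[nm]] <- format(out[[nm]], digits = 12, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}

#' @rdname write_assoc_results
#' @export
read_assoc_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  class(df) <- c("assoc_results", "data.frame")
  df
}
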