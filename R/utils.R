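# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

nm_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "neometab_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

format_error <- function(msg, ...) nm_error("neometab_format_error", msg, ...)
config_error <- function(msg, ...) nm_error("neometab_config_error", msg, ...)
domain_error <- function(msg, ...) nm_error("neometab_domain_error", msg, ...)

#' Derive a per-stage seed from a global seed
#'
#' Counter-based expansion of one global seed into independent stage seeds,
#' so that inserting a stage never reshuffles the randomness of later stages.
#' Kept within 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Stage counter (small non-negative integer).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1048573) * 2039 + 7 * stage) %% .Machine$integer.max
}

# Append plain-text log lines carried on a result object.
add_log <- function(x, lines) {
  attr(x, "log") <- c(attr(x, "log"), lines)
  x
}

#' Retrieve the processing log attached to a result
#' @param x An object returned by a pipeline stage.
#' @return Character vector of log lines (possibly empty).
#' @export
processing_log <- function(x) attr(x, "log") %||% character(0)
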