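#' Spectral match acceptance thresholds
#'
#' The MASST-style acceptance criteria for a library match: cosine strictly
#' greater than `min_cosine`, at least `min_matched_peaks` shared fragment
#' peaks, precursor (parent) mass difference strictly below
#' `parent_mass_tol`, and fragment pairing tolerance `fragment_tol`.
#'
#' @param min_cosine Minimum cosine, default 0.7 (strict >).
#' @param min_matched_peaks Minimum matched peak count, default 4.
#' @param parent_mass_tol Parent mass tolerance in Da, default 0.05 (strict <).
#' @param fragment_tol Fragment (ion) tolerance in Da, default 0.05.
#' @return An object of class `match_thresholds`.
#' @export
match_thresholds <- function(min_cosine = 0.7, min_matched_peaks = 4L,
                             parent_mass_tol = 0.05, fragment_tol = 0.05) {
  if (min_cosine <= 0 || min_cosine > 1)
    config_error("min_cosine must lie in (0, 1]")
  if (min_matched_peaks < 1 || parent_mass_tol <= 0 || fragment_tol <= 0)
    config_error("thresholds must be strictly positive")
  structure(list(min_cosine = min_cosine,
                 min_matched_peaks = as.integer(min_matched_peaks),
                 parent_mass_tol = parent_mass_tol, fragment_tol = fragment_tol),
            class = "match_thresholds")
}

#' Pair fragment peaks between two spectra
#'
#' One-to-one pairing of peaks with m/z difference at most `fragment_tol`:
#' candidate pairs are taken greedily by descending intensity product, ties
#' broken by the smaller m/z difference, each peak used at most once. The
#' greedy rule is deterministic; for small spectra it agrees with the optimal
#' assignment (see package tests).
#'
#' @param a,b [ms2_spectrum] objects.
#' @param fragment_tol Pairing tolerance in Da.
#' @return Integer matrix with columns `i` (peak index in `a`) and `j`
#'   (peak index in `b`); zero rows if nothing pairs.
#' @export
match_peaks <- function(a, b, fragment_tol = 0.05) {
  stopifnot(inherits(a, "ms2_spectrum"), inherits(b, "ms2_spectrum"))
  cand <- which(abs(outer(a$mz, b$mz, "-")) <= fragment_tol, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  prod <- a$intensity[cand[, 1]] * b$intensity[cand[, 2]]
  dmz <- abs(a$mz[cand[, 1]] - b$mz[cand[, 2]])
  o <- order(-prod, dmz, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  used_a <- logical(length(a$mz)); used_b <- logical(length(b$mz))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[r] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  colnames(out) <- c("i", "j")
  out[order(out[, 1]), , drop = FALSE]
}

#' Cosine similarity of two fragmentation spectra
#'
#' Normalized dot product over tolerance-paired peaks using raw intensities:
#' `sum(I_a * I_b over pairs) / (||I_a|| * ||I_b||)`, with the norms taken
#' over *all* peaks of each spectrum, so unmatched peaks penalize the score.
#' Symmetric, scale-invariant in intensities, bounded in `[0, 1]`, and exactly
#' 0 when no peaks pair. A square-root intensity transform is available since
#' library-search deployments differ.
#'
#' @param a,b [ms2_spectrum] objects.
#' @param fragment_tol Pairing tolerance in Da.
#' @param intensity_power Exponent applied to intensities before scoring
#'   (1 = raw, default; 0.5 = square-root weighting).
#' @return List with `cosine` and `n_matched`.
#' @export
cosine_score <- function(a, b, fragment_tol = 0.05, intensity_power = 1) {
  pairs <- match_peaks(a, b, fragment_tol)
  ia <- a$intensity^intensity_power
  ib <- b$intensity^intensity_power
  na_ <- sqrt(sum(ia^2)); nb_ <- sqrt(sum(ib^2))
  if (na_ == 0 || nb_ == 0) domain_error("spectrum with all-zero intensities")
  if (nrow(pairs) == 0) return(list(cosine = 0, n_matched = 0L))
  list(cosine = sum(ia[pairs[, 1]] * ib[pairs[, 2]]) / (na_ * nb_),
       n_matched = nrow(pairs))
}

#' MASST-style spectral library search
#'
#' Screens a query spectrum against a library, accepting matches that pass
#' all thresholds: parent mass difference strictly below `parent_mass_tol`,
#' cosine strictly above `min_cosine`, and at least `min_matched_peaks`
#' paired peaks. Results are sorted by descending cosine.
#'
#' @param query An [ms2_spectrum].
#' @param library_spectra List of [ms2_spectrum] objects.
#' @param thresholds A [match_thresholds].
#' @return Data frame (possibly empty) with `query_id`, `library_id`,
#'   `cosine`, `n_matched_peaks`, `parent_mass_diff`.
#' @export
library_search <- function(query, library_spectra,
                           thresholds = match_thresholds()) {
  stopifnot(inherits(query, "ms2_spectrum"), inherits(thresholds, "match_thresholds"))
  if (!length(library_spectra)) domain_error("empty spectral library")
  rows <- lapply(library_spectra, function(lib) {
    dmass <- abs(query$precursor_mz - lib$precursor_mz)
    if (dmass >= thresholds$parent_mass_tol) return(NULL)
    sc <- cosine_score(query, lib, thresholds$fragment_tol)
    if (sc$cosine <= thresholds$min_cosine) return(NULL)
    if (sc$n_matched < thresholds$min_matched_peaks) return(NULL)
    data.frame(query_id = query$spectrum_id, library_id = lib$spectrum_id,
               cosine = sc$cosine, n_matched_peaks = sc$n_matched,
               parent_mass_diff = dmass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(0), library_id = character(0),
                      cosine = numeric(0), n_matched_peaks = integer(0),
                      parent_mass_diff = numeric(0))
  out[order(-out$cosine), , drop = FALSE]
}
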