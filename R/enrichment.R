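#' Metabolite-class enrichment among significant features
#'
#' For each annotated metabolite class, builds the 2x2 table of (in class vs
#' not) by (significant vs not) over annotated features and computes the
#' two-sided Fisher exact p-value (point-probability rule: summing all tables
#' with probability not exceeding the observed one). Features without a class
#' annotation (`NA`) are excluded.
#'
#' @param sig_flags Logical per-feature significance indicator.
#' @param class_labels Character per-feature class annotation (`NA` allowed).
#' @return Data frame with one row per class: counts `a` (significant, in
#'   class), `b` (not significant, in class), `c` (significant, out of
#'   class), `d` (rest) and `p`.
#' @export
class_enrichment <- function(sig_flags, class_labels) {
  if (length(sig_flags) != length(class_labels))
    domain_error("sig_flags and class_labels must align")
  keep <- !is.na(class_labels)
  sig <- as.logical(sig_flags[keep])
  cls <- as.character(class_labels[keep])
  if (!length(cls)) domain_error("no annotated features")
  out <- lapply(sort(unique(cls)), function(cl) {
    inc <- cls == cl
    if (all(inc))
      domain_error("class '%s' covers all annotated features (degenerate table)", cl)
    a <- sum(inc & sig); b <- sum(inc & !sig)
    cc <- sum(!inc & sig); d <- sum(!inc & !sig)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    data.frame(class = cl, a = a, b = b, c = cc, d = d, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Energy-adjust a dietary intake
#'
#' @param intake Intake in g/day.
#' @param energy_nonalcoholic Non-alcoholic energy intake in kcal/day (> 0).
#' @return `intake / energy_nonalcoholic`.
#' @export
energy_adjust <- function(intake, energy_nonalcoholic) {
  if (any(is.na(energy_nonalcoholic)) || any(energy_nonalcoholic <= 0))
    domain_error("non-alcoholic energy intake must be > 0")
  intake / energy_nonalcoholic
}
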