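# Independent oracles and fixture builders used across the suite.

# --- small feature tables built in code ------------------------------------

make_table <- function(mat, plate = rep("p1", nrow(mat)),
                       order = seq_len(nrow(mat)),
                       qc = rep("analytical", nrow(mat))) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("s%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("f%02d", seq_len(ncol(mat)))
  feature_table(mat, plate = plate, injection_order = order, qc_flag = qc)
}

random_spectrum <- function(id, n_peaks, mz_range = c(50, 500)) {
  ms2_spectrum(id, runif(1, 100, 600),
               runif(n_peaks, mz_range[1], mz_range[2]),
               runif(n_peaks, 0.05, 1))
}

# --- exhaustive optimal-assignment cosine (<= ~7 peaks) ---------------------
# Enumerates all one-to-one peak assignments within tolerance and returns the
# maximum achievable dot product / norms.
assignment_cosine <- function(a, b, tol) {
  na_ <- length(a$mz); nb_ <- length(b$mz)
  allowed <- abs(outer(a$mz, b$mz, "-")) <= tol
  best <- 0
  recurse <- function(i, used_b, acc) {
    if (i > na_) { best <<- max(best, acc); return(invisible()) }
    recurse(i + 1, used_b, acc)  # leave peak i unmatched
    for (j in which(allowed[i, ] & !used_b)) {
      used_b[j] <- TRUE
      recurse(i + 1, used_b, acc + a$intensity[i] * b$intensity[j])
      used_b[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, nb_), 0)
  best / (sqrt(sum(a$intensity^2)) * sqrt(sum(b$intensity^2)))
}

# --- two-sided Fisher exact p by full hypergeometric enumeration ------------
fisher_enum <- function(a, b, c_, d) {
  m <- a + b; n_ <- c_ + d; k <- a + c_
  xs <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(xs, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- per-pair residual-regression partial correlation -----------------------
pcorr_residual_oracle <- function(X, i, j) {
  Z <- X[, -c(i, j), drop = FALSE]
  D <- cbind(1, Z)
  ri <- stats::lm.fit(D, X[, i])$residuals
  rj <- stats::lm.fit(D, X[, j])$residuals
  stats::cor(ri, rj)
}

# --- spectra with a known shared-peak structure -----------------------------
# `n_shared` identical peaks plus one extra query peak whose intensity tunes
# the cosine to `target_cosine`.
spectrum_pair <- function(n_shared, target_cosine, precursor_q = 160.130,
                         precursor_l = 160.133) {
  mz <- seq(60, by = 17.3, length.out = n_shared)
  lib <- ms2_spectrum("lib", precursor_l, mz, rep(1, n_shared))
  t2 <- n_shared / target_cosine^2 - n_shared
  qry <- ms2_spectrum("query", precursor_q, c(mz, max(mz) + 40),
                      c(rep(1, n_shared), sqrt(t2)))
  list(query = qry, library = lib)
}
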