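#' Generate a synthetic adult cohort with genotypes, diet and a metabolite
#'
#' Emulates an adult population cohort used to study genetic and dietary
#' determinants of a circulating metabolite. Genotypes are Hardy-Weinberg
#' dosages (0/1/2) with minor-allele frequencies drawn uniformly from
#' (0.05, 0.5). The metabolite is built additively:
#' `y = sum_j beta_j * genotype_j + gamma * dairy + noise`, with each causal
#' SNP scaled to explain exactly its stated variance fraction (on standardized
#' dosages) and the dairy coefficient set so the Spearman correlation between
#' the metabolite and energy-adjusted dairy intake is approximately
#' `diet_corr`. The diet table carries age, sex, BMI, non-alcoholic energy
#' intake (kcal/day) and six energy-adjustable dietary intake groups (g/day).
#'
#' @param n Number of participants.
#' @param n_snps Number of SNPs.
#' @param causal `NULL` or data frame with columns `snp` (index or id) and
#'   `variance_explained` (each in `[0, 0.05]`).
#' @param diet_corr Target Spearman correlation between the metabolite and
#'   energy-adjusted dairy intake.
#' @param seed Integer seed.
#' @return List with `genotypes` (n x n_snps dosage matrix), `diet` (data
#'   frame), `metabolite` (numeric vector) and `truth` (planted effects).
#' @export
generate_adult_cohort <- function(n, n_snps, causal = NULL, diet_corr = 0,
                                  seed = 1L) {
  if (!is.null(causal)) {
    causal <- as.data.frame(causal)
    if (!all(c("snp", "variance_explained") %in% names(causal)))
      config_error("causal needs columns snp, variance_explained")
    if (any(causal$variance_explained < 0 | causal$variance_explained > 0.05))
      config_error("per-SNP variance_explained must lie in [0, 0.05]")
  }
  # diet_corr targets the *Spearman* correlation; the coefficient on the
  # (near-normal) dairy score is therefore the bivariate-normal inverse of
  # the rank correlation, 2 * sin(pi * rho_s / 6)
  gamma <- 2 * sin(pi * diet_corr / 6)
  ve_total <- sum(causal$variance_explained %||% 0) + gamma^2
  if (ve_total >= 1)
    config_error("total explained variance (%.3f) must be < 1", ve_total)

  set.seed(stage_seed(seed, 3L))
  snp_ids <- sprintf("rs%05d", seq_len(n_snps))
  maf <- stats::runif(n_snps, 0.05, 0.5)
  G <- matrix(stats::rbinom(n * n_snps, 2L, rep(maf, each = n)), n, n_snps,
              dimnames = list(sprintf("S%05d", seq_len(n)), snp_ids))

  age <- stats::runif(n, 46, 68)
  sex <- stats::rbinom(n, 1, 0.45)
  bmi <- rnorm_clamped(n, 25.8, 3.9, 16, 45)
  energy <- stats::rlnorm(n, log(2200), 0.22)
  intake <- function(mean_g, sdlog) stats::rlnorm(n, log(mean_g), sdlog)
  diet <- data.frame(
    sample_id = rownames(G), age = age, sex = sex, bmi = bmi,
    energy_nonalcoholic = energy,
    dairy = intake(350, 0.45), meat = intake(130, 0.40),
    fish = intake(45, 0.55), fruit_vegetables = intake(330, 0.40),
    cereals = intake(200, 0.35), potatoes = intake(120, 0.50),
    stringsAsFactors = FALSE
  )

  std <- function(v) (v - mean(v)) / stats::sd(v)
  dairy_score <- std(log(energy_adjust(diet$dairy, diet$energy_nonalcoholic)))

  y <- stats::rnorm(n, 0, sqrt(1 - ve_total))
  beta <- numeric(0)
  causal_idx <- integer(0)
  if (!is.null(causal) && nrow(causal)) {
    causal_idx <- if (is.numeric(causal$snp)) as.integer(causal$snp)
                  else match(as.character(causal$snp), snp_ids)
    if (any(is.na(causal_idx)) || any(causal_idx < 1 | causal_idx > n_snps))
      config_error("causal SNP id(s) not present among the %d SNPs", n_snps)
    beta <- sqrt(causal$variance_explained)
    for (k in seq_along(causal_idx))
      y <- y + beta[k] * std(G[, causal_idx[k]])
  }
  y <- y + gamma * dairy_score

  list(
    genotypes = G, diet = diet, metabolite = y,
    truth = list(
      causal = if (length(causal_idx))
        data.frame(snp = snp_ids[causal_idx],
                   variance_explained = causal$variance_explained,
                   beta_std = beta, stringsAsFactors = FALSE)
      else data.frame(snp = character(0), variance_explained = numeric(0),
                      beta_std = numeric(0)),
      diet_corr = diet_corr, dairy_gamma = gamma,
      maf = stats::setNames(maf, snp_ids)
    )
  )
}
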