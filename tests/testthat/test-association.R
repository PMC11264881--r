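test_that("unadjusted binary-feature fit equals the cross-product odds ratio", {
  y <- rep(c(1, 0), c(100, 100))
  x <- c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85))
  res <- fit_feature_assoc(y, x, mode = "binary_presence")
  expect_equal(res$estimate, (30 * 85) / (15 * 70), tolerance = 1e-6)
  expect_lte(res$ci_low, res$estimate)
  expect_gte(res$ci_high, res$estimate)
  expect_equal(res$n_used, 200L)
})

test_that("quartile mode emits Q1 as the fixed reference", {
  set.seed(2)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(0.4 * x))
  res <- fit_feature_assoc(y, quartile_bins(x), mode = "quartile")
  expect_equal(nrow(res), 4L)
  expect_equal(res$estimate[res$quartile == 1], 1)
  expect_true(all(is.finite(res$estimate[res$quartile != 1])))
})

test_that("separation triggers the flagged penalized-likelihood fallback", {
  y <- rep(c(1, 0), each = 15)
  x <- rep(c(1, 0), each = 15)  # complete separation
  res <- fit_feature_assoc(y, x, mode = "binary_presence")
  expect_true(res$flagged)
  expect_true(is.finite(res$estimate) && res$estimate > 1)
  expect_true(is.finite(res$p))
})

test_that("BH adjustment matches the hand step-up and is permutation-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.8 * 4 / 60, 0.8), tolerance = 1e-9)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(numeric(0)), class = "neometab_domain_error")
  set.seed(5)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-12))  # monotone in p
})

test_that("rank AUC equals exhaustive pair enumeration", {
  expect_equal(auc_single(c(0.9, 0.7, 0.4, 0.8), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_single(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_single(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_single(1:4, rep(1, 4)), class = "neometab_domain_error")
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    x <- sample(rnorm(n - 3), n, replace = TRUE)  # forces some ties
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    enum <- mean(ifelse(x[pairs$i] > x[pairs$j], 1,
                        ifelse(x[pairs$i] == x[pairs$j], 0.5, 0)))
    expect_equal(auc_single(x, y), enum, tolerance = 1e-12)
  }
})

test_that("cohort-table statistics reproduce printed values", {
  season <- cbind(cases = c(168, 180, 190, 201), controls = c(168, 185, 188, 198))
  ts <- contingency_chisq(season)
  expect_equal(ts$df, 3)
  expect_equal(round(ts$p, 2), 0.99)

  fh <- rbind(c(222, 517), c(138, 601))
  tf <- contingency_chisq(fh)
  expect_equal(tf$statistic, 25.9, tolerance = 0.01)
  expect_lt(tf$p, 0.001)

  same <- rbind(c(10, 20), c(10, 20))
  t0 <- contingency_chisq(same)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_error(contingency_chisq(rbind(c(0, 0), c(1, 2))),
               class = "neometab_domain_error")
})

test_that("pooled t-test follows the closed form", {
  tt <- two_sample_t(c(0, 1), c(1, 2))
  expect_equal(tt$statistic, -sqrt(2), tolerance = 1e-6)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 0.292893, tolerance = 1e-4)
  eq <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_error(two_sample_t(1, c(1, 2)), class = "neometab_domain_error")
  expect_error(two_sample_t(c(2, 2), c(2, 2)), class = "neometab_domain_error")
})

test_that("the MWAS ranks planted effects first and is deterministic", {
  cfg <- sim_config(n_pairs = 250, n_features = 80, n_plates = 4, seed = 71,
                    drift_amplitude = 0,
                    signal_features = data.frame(
                      feature_id = c("F0003", "F0050"),
                      mode = c("continuous", "binary"), true_or = c(2.3, 2.3)))
  coh <- generate_neonatal_cohort(cfg)
  tab <- generate_feature_matrix(coh$samples, coh$truth, cfg)
  proc <- process_features(tab, impute = "half_min")
  res1 <- run_mwas(proc, coh$samples, model_spec("model1"))
  res2 <- run_mwas(proc, coh$samples, model_spec("model1"))
  expect_equal(res1$p, res2$p)
  top2 <- res1$feature_id[order(res1$p)][1:2]
  expect_setequal(top2, c("F0003", "F0050"))
  expect_true(all(res1$q >= res1$p - 1e-12 | res1$q <= 1))
  expect_equal(sort(unique(res1$mode)),
               c("binary_presence", "continuous_per_sd"))

  # model 2 adds the confounder set and still runs
  res_m2 <- run_mwas(proc, coh$samples, model_spec("model2"))
  expect_equal(nrow(res_m2), nrow(res1))
})

test_that("stratified analysis detects a diagnosis-age-specific effect", {
  set.seed(61)
  n_pairs <- 739
  power_hits <- 0; null_low <- 0
  reps <- 20
  for (r in 1:reps) {
    n_case <- n_pairs; n_ctrl <- n_pairs
    aad <- runif(n_case, 2, 10)
    early <- aad < 6
    y <- c(rep(1, n_case), rep(0, n_ctrl))
    x_diff <- c(rnorm(n_case, ifelse(early, log(2.2), 0)), rnorm(n_ctrl))
    res <- stratified_interaction(y, x_diff, NULL,
                                  c(aad, rep(NA, n_ctrl)), split = 6)
    if (res$p_interaction < 0.05) power_hits <- power_hits + 1
    x_same <- c(rnorm(n_case, log(1.8)), rnorm(n_ctrl))
    res0 <- stratified_interaction(y, x_same, NULL,
                                   c(aad, rep(NA, n_ctrl)), split = 6)
    if (res0$p_interaction < 0.05) null_low <- null_low + 1
  }
  expect_gte(power_hits, 0.7 * reps)   # differential effect found
  expect_lte(null_low, 0.25 * reps)    # equal effect rarely flagged
  expect_true(res$controls_shared)
  expect_gt(res$or_early, res$or_late)
  expect_error(stratified_interaction(c(1, 1, 0, 0), rnorm(4), NULL,
                                      c(2, 3, NA, NA), split = 1),
               class = "neometab_domain_error")
})
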