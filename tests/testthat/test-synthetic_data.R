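test_that("generated cohorts honour the matching calipers and design margins", {
  cfg <- sim_config(n_pairs = 739, n_features = 5, seed = 101)
  coh <- generate_neonatal_cohort(cfg)
  s <- coh$samples
  expect_equal(nrow(s), 2 * 739)
  expect_true(all(table(s$pair_id) == 2))
  by_pair <- split(s, s$pair_id)
  ga_diff <- vapply(by_pair, function(p)
    abs(diff(p$gestational_age)), numeric(1))
  age_diff <- vapply(by_pair, function(p)
    abs(diff(p$age_at_sampling)), numeric(1))
  bd_diff <- vapply(by_pair, function(p)
    abs(as.numeric(diff(as.Date(p$birth_date)))), numeric(1))
  expect_true(all(ga_diff <= 4 / 7 + 1e-9))   # +/- 4 days on the week scale
  expect_true(all(age_diff <= 1 + 1e-9))
  expect_true(all(bd_diff <= 14))
  expect_true(all(s$gestational_age >= 34 & s$gestational_age <= 42))
  expect_true(all(s$age_at_sampling >= 3 & s$age_at_sampling <= 8))
  expect_true(all(is.na(s$age_at_diagnosis[s$group == "control"])))

  # family-history counts near the design rates (binomial mean 221.7 / 138.2)
  fh_case <- sum(s$family_history[s$group == "case"])
  fh_ctrl <- sum(s$family_history[s$group == "control"])
  expect_lt(abs(fh_case - 739 * 0.300), 4 * sqrt(739 * 0.300 * 0.700))
  expect_lt(abs(fh_ctrl - 739 * 0.187), 4 * sqrt(739 * 0.187 * 0.813))
})

test_that("season labels follow the meteorological birth-date rule", {
  cfg <- sim_config(n_pairs = 200, n_features = 2, seed = 5)
  s <- generate_neonatal_cohort(cfg)$samples
  m <- as.integer(format(as.Date(s$birth_date), "%m"))
  expected <- ifelse(m %in% c(12, 1, 2), "winter",
              ifelse(m %in% 3:5, "spring",
              ifelse(m %in% 6:8, "summer", "autumn")))
  expect_identical(s$season, expected)
})

test_that("polygenic score separation matches the binormal AUC target", {
  cfg <- sim_config(n_pairs = 5000, n_features = 2, prs_auc = 0.58, seed = 21)
  s <- generate_neonatal_cohort(cfg)$samples
  auc <- auc_single(s$prs, as.numeric(s$group == "case"))
  expect_gt(auc, 0.56); expect_lt(auc, 0.60)

  # AUC 0.5 means no shift at all
  cfg0 <- sim_config(n_pairs = 3000, n_features = 2, prs_auc = 0.5, seed = 22)
  s0 <- generate_neonatal_cohort(cfg0)$samples
  expect_lt(abs(mean(s0$prs[s0$group == "case"]) -
                mean(s0$prs[s0$group == "control"])), 0.08)
})

test_that("feature matrices are seed-deterministic and respect presence targets", {
  cfg <- sim_config(n_pairs = 500, n_features = 20, n_plates = 4,
                    presence_targets = c(0.20, rep(0.9, 19)), seed = 33)
  coh <- generate_neonatal_cohort(cfg)
  t1 <- generate_feature_matrix(coh$samples, coh$truth, cfg)
  t2 <- generate_feature_matrix(coh$samples, coh$truth, cfg)
  expect_identical(t1$intensities, t2$intensities)
  expect_identical(t1$injection_order, t2$injection_order)

  frac <- presence_fraction(t1)
  expect_gt(frac[1], 0.16); expect_lt(frac[1], 0.24)
  expect_true(all(frac[-1] > 0.85))
})

test_that("a noise-free configuration yields a complete undrifted matrix", {
  cfg <- sim_config(n_pairs = 40, n_features = 8, n_plates = 2,
                    drift_amplitude = 0, batch_sd = 0,
                    presence_targets = rep(1, 8), seed = 9)
  coh <- generate_neonatal_cohort(cfg)
  tab <- generate_feature_matrix(coh$samples, coh$truth, cfg)
  expect_false(anyNA(tab$intensities))
  # QC replicate RSD reflects analytical noise only (5% log-scale)
  rep_rsd <- qc_report(tab, qc_type = "plate_pool", per_plate = TRUE)$rsd
  expect_true(all(rep_rsd < 15))
})

test_that("planted binary effects shift the presence odds by the target OR", {
  cfg <- sim_config(n_pairs = 4000, n_features = 4, n_plates = 4, seed = 55,
                    signal_features = data.frame(feature_id = "F0002",
                                                 mode = "binary", true_or = 1.7))
  coh <- generate_neonatal_cohort(cfg)
  tab <- generate_feature_matrix(coh$samples, coh$truth, cfg)
  pres <- binarize(analytical_samples(tab)$intensities[, "F0002"])
  grp <- coh$samples$group[match(sample_ids(analytical_samples(tab)),
                                 coh$samples$sample_id)]
  p1 <- mean(pres[grp == "case"]); p0 <- mean(pres[grp == "control"])
  or_hat <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_gt(or_hat, 1.45); expect_lt(or_hat, 2.0)
})

test_that("adult cohort plants SNP variance and dietary correlation", {
  ad <- generate_adult_cohort(4000, 30,
                              causal = data.frame(snp = 7, variance_explained = 0.03),
                              diet_corr = 0.18, seed = 12)
  expect_equal(dim(ad$genotypes), c(4000L, 30L))
  expect_true(all(ad$genotypes %in% 0:2))
  g <- scale(ad$genotypes[, 7])
  expect_lt(abs(cor(ad$metabolite, g)^2 - 0.03), 0.012)
  adj <- energy_adjust(ad$diet$dairy, ad$diet$energy_nonalcoholic)
  expect_lt(abs(cor(ad$metabolite, adj, method = "spearman") - 0.18), 0.04)
  expect_error(
    generate_adult_cohort(100, 10,
                          causal = data.frame(snp = 1, variance_explained = 0.2)),
    class = "neometab_config_error")
  expect_error(sim_config(fh_rate_case = 1.2), class = "neometab_config_error")
})
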