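test_that("qc_rsd matches the hand-computed definition", {
  expect_equal(qc_rsd(c(10, 10, 10)), 0)
  expect_equal(qc_rsd(c(9, 11)), 100 * sqrt(2) / 10, tolerance = 1e-9)
  expect_error(qc_rsd(10), class = "neometab_domain_error")
  expect_error(qc_rsd(c(1, -1, 2)), class = "neometab_domain_error")
})

test_that("constant QC values give an identity correction", {
  curve <- fit_drift_curve(1:10, rep(5, 10))
  expect_equal(predict_drift(curve, 1:10), rep(5, 10), tolerance = 1e-9)
  expect_equal(curve$reference, 5)

  mat <- matrix(rlnorm(40, 8, 0.5), 10, 4)
  tab <- make_table(rbind(mat, matrix(5, 4, 4)),
                    order = 1:14,
                    qc = c(rep("analytical", 10), rep("plate_pool", 4)))
  corrected <- apply_drift_correction(tab, fit_drift_model(tab))
  expect_equal(corrected$intensities, tab$intensities, tolerance = 1e-9)
})

test_that("exactly linear QC drift is reproduced by the degree-1 fit", {
  ord <- seq(2, 40, by = 4)
  vals <- 100 + 3 * ord
  curve <- fit_drift_curve(ord, vals, span = 1, degree = 1)
  expect_equal(predict_drift(curve, ord), vals, tolerance = 1e-8)
  # clamped (not extrapolated) outside the QC order range (last order 38)
  expect_equal(predict_drift(curve, 1000), 100 + 3 * 38, tolerance = 1e-8)
})

test_that("too few QC points raise an insufficient-QC condition", {
  expect_error(fit_drift_curve(1:3, c(1, 2, 3)),
               class = "neometab_insufficient_qc")
  expect_error(fit_drift_curve(1:5, c(1, 2, -3, 4, 5)),
               class = "neometab_domain_error")
})

test_that("drift correction is scale-equivariant and mask-preserving", {
  set.seed(14)
  cfg <- sim_config(n_pairs = 40, n_features = 6, n_plates = 2,
                    drift_amplitude = 0.4,
                    presence_targets = c(0.6, rep(1, 5)), seed = 4)
  coh <- generate_neonatal_cohort(cfg)
  tab <- generate_feature_matrix(coh$samples, coh$truth, cfg)
  corr1 <- apply_drift_correction(tab, fit_drift_model(tab))
  expect_identical(is.na(corr1$intensities), is.na(tab$intensities))

  k <- 3.7
  tab_k <- tab
  tab_k$intensities[, 2] <- tab$intensities[, 2] * k
  corr_k <- apply_drift_correction(tab_k, fit_drift_model(tab_k))
  expect_equal(corr_k$intensities[, 2], corr1$intensities[, 2] * k,
               tolerance = 1e-9)
})

test_that("known synthetic drift is removed from QC replicates", {
  cfg <- sim_config(n_pairs = 120, n_features = 30, n_plates = 3,
                    drift_amplitude = 0.5, presence_targets = rep(1, 30),
                    seed = 17)
  coh <- generate_neonatal_cohort(cfg)
  tab <- generate_feature_matrix(coh$samples, coh$truth, cfg)
  pre <- qc_report(tab, qc_type = "plate_pool")$rsd
  post <- qc_report(apply_drift_correction(tab, fit_drift_model(tab)),
                    qc_type = "plate_pool")$rsd
  expect_gt(mean(pre), 15)
  expect_lt(mean(post), 5)
  expect_gt(mean(post < pre), 0.95)  # RSD falls for nearly every feature
})

test_that("plate-median batch correction removes a constructed offset", {
  set.seed(8)
  base <- rlnorm(40, 8, 0.3)
  mat <- matrix(c(base, base * 2), ncol = 1)
  tab <- make_table(mat, plate = rep(c("p1", "p2"), each = 40),
                    order = c(1:40, 1:40))
  out <- correct_batch(tab, "plate_median")
  meds <- tapply(log(out$intensities[, 1]), out$plate, median)
  expect_lt(abs(diff(meds)), 1e-8)

  expect_identical(correct_batch(tab, "none")$intensities, tab$intensities)
  one <- make_table(matrix(base, ncol = 1), order = 1:40)
  expect_equal(correct_batch(one, "plate_median")$intensities, one$intensities,
               tolerance = 1e-12)
})

test_that("imputation completes the matrix and leaves observed cells alone", {
  set.seed(31)
  n <- 60
  latent <- rnorm(n)
  mat <- exp(sapply(1:6, function(j) 8 + 0.8 * latent + rnorm(n, 0, 0.3)))
  colnames(mat) <- sprintf("f%d", 1:6)
  miss <- matrix(runif(length(mat)) < 0.12, n, 6)
  mat_na <- mat; mat_na[miss] <- NA
  filled <- impute_halfmin_tree(mat_na)
  expect_false(anyNA(filled))
  expect_true(all(filled > 0))
  expect_equal(filled[!miss], mat[!miss], tolerance = 1e-12)
})
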