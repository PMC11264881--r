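test_that("cosine score handles identical, partial and disjoint spectra", {
  a <- ms2_spectrum("a", 160.13, c(58.065, 59.07, 101.1, 150.1), c(100, 35, 5, 20))
  expect_equal(cosine_score(a, a)$cosine, 1, tolerance = 1e-12)
  expect_equal(cosine_score(a, a)$n_matched, 4L)

  b1 <- ms2_spectrum("b1", 160.13, c(100.0, 150.0), c(1, 1))
  b2 <- ms2_spectrum("b2", 160.13, c(100.0, 200.0), c(1, 1))
  sc <- cosine_score(b1, b2, 0.05)
  expect_equal(sc$cosine, 0.5)
  expect_equal(sc$n_matched, 1L)

  d <- ms2_spectrum("d", 160.13, c(300, 400), c(1, 1))
  sc0 <- cosine_score(b1, d, 0.05)
  expect_equal(sc0$cosine, 0)
  expect_equal(sc0$n_matched, 0L)
})

test_that("cosine is symmetric, scale-invariant and bounded", {
  set.seed(71)
  for (rep in 1:20) {
    a <- random_spectrum("a", sample(2:8, 1))
    b <- random_spectrum("b", sample(2:8, 1))
    sab <- cosine_score(a, b, 0.3)
    sba <- cosine_score(b, a, 0.3)
    expect_equal(sab$cosine, sba$cosine, tolerance = 1e-12)
    expect_gte(sab$cosine, 0); expect_lte(sab$cosine, 1 + 1e-12)
    a2 <- ms2_spectrum("a2", a$precursor_mz, a$mz, a$intensity * 37.5)
    expect_equal(cosine_score(a2, b, 0.3)$cosine, sab$cosine, tolerance = 1e-12)
  }
})

test_that("greedy pairing is one-to-one, within tolerance, and near-optimal", {
  A <- ms2_spectrum("A", 200, c(100.00, 150.00), c(1, 1))
  B <- ms2_spectrum("B", 200, c(100.03, 200.00), c(1, 1))
  pairs <- match_peaks(A, B, 0.05)
  expect_equal(nrow(pairs), 1L)
  expect_equal(unname(pairs[1, ]), c(1L, 1L))

  set.seed(90)
  worse <- 0
  for (rep in 1:200) {
    a <- random_spectrum("a", sample(2:6, 1), mz_range = c(50, 120))
    b <- random_spectrum("b", sample(2:6, 1), mz_range = c(50, 120))
    tol <- runif(1, 0.5, 8)  # dense m/z so multi-candidate pairings occur
    pairs <- match_peaks(a, b, tol)
    if (nrow(pairs)) {
      expect_lte(max(abs(a$mz[pairs[, 1]] - b$mz[pairs[, 2]])), tol)
      expect_false(anyDuplicated(pairs[, 1]) > 0)
      expect_false(anyDuplicated(pairs[, 2]) > 0)
    }
    greedy <- cosine_score(a, b, tol)$cosine
    optimal <- assignment_cosine(a, b, tol)
    expect_lte(greedy, optimal + 1e-9)  # greedy never exceeds the optimum
    if (greedy < optimal - 1e-9) worse <- worse + 1
  }
  # the intensity-product greedy rule attains the optimum essentially always
  # on small spectra; allow a handful of constructed-tie exceptions
  expect_lte(worse, 4)
})

test_that("library search applies all MASST acceptance thresholds", {
  pair_ok <- spectrum_pair(4, 0.81)
  hits <- library_search(pair_ok$query, list(pair_ok$library))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$cosine, 0.81, tolerance = 1e-9)
  expect_equal(hits$n_matched_peaks, 4L)
  expect_lt(hits$parent_mass_diff, 0.01)

  # high cosine but only 3 shared peaks: rejected
  pair_few <- spectrum_pair(3, 0.95)
  expect_equal(nrow(library_search(pair_few$query, list(pair_few$library))), 0L)

  # cosine below threshold: rejected
  pair_low <- spectrum_pair(4, 0.65)
  expect_equal(nrow(library_search(pair_low$query, list(pair_low$library))), 0L)

  # parent mass off: rejected even with perfect cosine
  q <- ms2_spectrum("q", 161.0, c(60, 80, 100, 120), rep(1, 4))
  l <- ms2_spectrum("l", 160.13, c(60, 80, 100, 120), rep(1, 4))
  expect_equal(nrow(library_search(q, list(l))), 0L)

  # identical query: top hit cosine 1, sorted first
  lib <- list(pair_ok$library, pair_low$library,
              ms2_spectrum("self", pair_ok$query$precursor_mz,
                           pair_ok$query$mz, pair_ok$query$intensity))
  hits2 <- library_search(pair_ok$query, lib)
  expect_equal(hits2$library_id[1], "self")
  expect_equal(hits2$cosine[1], 1, tolerance = 1e-12)
  expect_error(library_search(q, list()), class = "neometab_domain_error")
})

test_that("small m/z jitter and intensity noise keep parent matches strong", {
  set.seed(15)
  for (rep in 1:20) {
    a <- random_spectrum("a", sample(4:9, 1))
    jit <- ms2_spectrum("j", a$precursor_mz,
                        a$mz + runif(length(a$mz), -0.02, 0.02),
                        a$intensity * exp(rnorm(length(a$mz), 0, 0.05)))
    expect_gt(cosine_score(a, jit, 0.05)$cosine, 0.95)
  }
})
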