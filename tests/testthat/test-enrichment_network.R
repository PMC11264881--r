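test_that("Fisher enrichment matches full hypergeometric enumeration", {
  # frozen small-table values computed by enumeration: C(8,4) = 70 tables
  flags <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  cls <- c(rep("acylcarnitine", 4), rep("other", 4))
  res <- class_enrichment(flags, cls)
  expect_equal(res$p[res$class == "acylcarnitine"], 34 / 70, tolerance = 1e-9)

  res2 <- class_enrichment(c(rep(TRUE, 5), rep(FALSE, 5)),
                           c(rep("A", 5), rep("B", 5)))
  expect_equal(res2$p[res2$class == "A"], 2 / 252, tolerance = 1e-9)

  # nothing significant: every class p-value is 1
  res3 <- class_enrichment(rep(FALSE, 8), cls)
  expect_true(all(res3$p == 1))

  # randomized small tables against the enumeration oracle
  set.seed(44)
  for (rep in 1:30) {
    n <- sample(8:30, 1)
    flags <- runif(n) < runif(1, 0.2, 0.7)
    cls <- sample(c("X", "Y"), n, replace = TRUE)
    if (length(unique(cls)) < 2) next
    res <- class_enrichment(flags, cls)
    rX <- res[res$class == "X", ]
    expect_equal(rX$p, fisher_enum(rX$a, rX$b, rX$c, rX$d), tolerance = 1e-9)
    # invariance to swapping the 2x2 roles
    expect_equal(fisher_enum(rX$a, rX$c, rX$b, rX$d), rX$p, tolerance = 1e-9)
  }

  expect_error(class_enrichment(c(TRUE, FALSE), c("A", "A")),
               class = "neometab_domain_error")
})

test_that("energy adjustment is plain division with a positivity guard", {
  expect_equal(energy_adjust(50, 2000), 0.025)
  expect_equal(energy_adjust(0, 2000), 0)
  expect_error(energy_adjust(50, 0), class = "neometab_domain_error")
})

test_that("precision-matrix partial correlations equal the residual oracle", {
  set.seed(18)
  for (rep in 1:8) {
    n <- 200; p <- sample(4:10, 1)
    X <- matrix(rnorm(n * p), n, p) %*%
      (diag(p) + matrix(runif(p * p, -0.2, 0.2), p, p))
    pc <- partial_corr_matrix(X)
    for (pair in list(c(1, 2), c(2, p), c(1, p))) {
      i <- pair[1]; j <- pair[2]
      expect_equal(pc$rho[i, j], pcorr_residual_oracle(X, i, j),
                   tolerance = 1e-8)
    }
    expect_equal(pc$rho, t(pc$rho), tolerance = 1e-12)
    expect_equal(pc$df, n - p)
  }
})

test_that("orthogonal columns have zero partial correlation", {
  n <- 64
  X <- qr.Q(qr(scale(matrix(rnorm(n * 5), n, 5), scale = FALSE)))
  pc <- partial_corr_matrix(X)
  off <- pc$rho[upper.tri(pc$rho)]
  expect_true(all(abs(off) < 1e-10))
})

test_that("conditioning on a sum induces the known negative partial correlation", {
  set.seed(23)
  n <- 10000
  x <- rnorm(n); y <- rnorm(n); z <- x + y
  pc <- partial_corr_matrix(cbind(x, y, z + rnorm(n, 0, 1e-6)))
  expect_lt(pc$rho["x", "y"], -0.9)  # near -1 given z ~ x + y
  expect_equal(pc$rho["x", "y"], pcorr_residual_oracle(cbind(x, y, z), 1, 2),
               tolerance = 1e-3)
})

test_that("exact mode refuses n <= p and ridge mode is flagged", {
  X <- matrix(rnorm(5 * 8), 5, 8)
  expect_error(partial_corr_matrix(X), class = "neometab_domain_error")
  pc <- partial_corr_matrix(X, method = "ridge", lambda = 0.5)
  expect_identical(pc$method, "ridge")
  expect_equal(pc$lambda, 0.5)
})

test_that("partial Spearman reduces to plain Spearman without covariates", {
  set.seed(27)
  x <- rnorm(100); y <- 0.4 * x + rnorm(100)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(partial_spearman(x, x)$rho, 1)
  expect_error(partial_spearman(rep(1, 50), rnorm(50)),
               class = "neometab_domain_error")
  # adjusting away a shared covariate kills an induced correlation
  z <- rnorm(200)
  a <- z + rnorm(200, 0, 0.3); b <- z + rnorm(200, 0, 0.3)
  expect_gt(partial_spearman(a, b)$rho, 0.7)
  expect_lt(abs(partial_spearman(a, b, cbind(z))$rho), 0.25)
})

test_that("planted dietary correlation is recovered through the full path", {
  ad <- generate_adult_cohort(3714, 10, diet_corr = 0.18, seed = 88)
  adj <- energy_adjust(ad$diet$dairy, ad$diet$energy_nonalcoholic)
  ps <- partial_spearman(ad$metabolite, adj,
                         ad$diet[, c("age", "sex", "bmi")])
  expect_gt(ps$rho, 0.14); expect_lt(ps$rho, 0.22)
  expect_lt(ps$p, 1e-10)
})
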