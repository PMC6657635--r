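test_that("penetrance tables have the advertised shape and heritability", {
  m0 <- penetrance_model("null", base = 2)
  expect_true(all(m0$table == 2))
  expect_equal(m0$heritability_label, 0)
  expect_error(penetrance_model("null", heritability = 0.2), "no effect")

  mx <- penetrance_model("xor", gain = 1.5, maf = 0.2, base = 1)
  idx <- as.matrix(expand.grid(0:2, 0:2))
  expect_equal(mx$table[idx + 1],
               1 + 1.5 * ((idx[, 1] + idx[, 2]) %% 2 == 1))
  mt <- penetrance_model("threshold", gain = 2, maf = 0.4)
  expect_equal(mt$table[1, ], rep(1, 3), ignore_attr = TRUE)
  expect_equal(mt$table[2:3, 2:3], matrix(3, 2, 2), ignore_attr = TRUE)

  # calibrated gain reproduces the requested heritability
  for (h in c(0.05, 0.2, 0.4)) {
    mh <- penetrance_model("xor", maf = 0.2, heritability = h)
    expect_equal(table_heritability(mh), h, tolerance = 1e-10)
    mh2 <- penetrance_model("threshold", maf = 0.4, heritability = h)
    expect_equal(table_heritability(mh2), h, tolerance = 1e-10)
  }
  expect_error(penetrance_model("xor", maf = 0.6), "MAF")
})

test_that("genotypes follow HWE at the requested MAF", {
  X <- simulate_genotypes(10000, 3, maf = 0.5, seed = 2)
  expect_true(all(X %in% 0:2))
  # genotype frequencies ~ (0.25, 0.5, 0.25)
  frq <- tabulate(X[, 1] + 1, 3) / 10000
  expect_gt(chisq.test(tabulate(X[, 1] + 1, 3),
                       p = c(0.25, 0.5, 0.25))$p.value, 0.001)
  # mean allele count within 3 binomial SEs of 2*MAF
  X2 <- simulate_genotypes(5000, 4, maf = 0.2, seed = 3)
  se <- sqrt(2 * 0.2 * 0.8 / 5000)
  expect_lt(max(abs(colMeans(X2) - 0.4)), 3 * se)
  # degenerate MAF limit: essentially all homozygous major
  X3 <- simulate_genotypes(1000, 1, maf = 1e-12, seed = 4)
  expect_true(all(X3 == 0))
  expect_error(simulate_genotypes(10, 2, maf = 0), "MAF")
  # determinism
  expect_identical(simulate_genotypes(50, 5, 0.3, seed = 9),
                   simulate_genotypes(50, 5, 0.3, seed = 9))
})

test_that("bivariate normal phenotypes have cell means f, unit variance, correlation rho", {
  n <- 50000
  X <- simulate_genotypes(n, 2, maf = 0.4, seed = 5)
  m0 <- penetrance_model("null", base = 1.7)
  Y <- phenotypes_bivariate_normal(X, m0, rho = 0, seed = 6)
  se <- 1 / sqrt(n)
  expect_lt(max(abs(colMeans(Y) - 1.7)), 3 * se)
  expect_lt(max(abs(apply(Y, 2, var) - 1)), 3 * sqrt(2 / n))
  expect_lt(abs(cor(Y[, 1], Y[, 2])), 3 * se)

  Yr <- phenotypes_bivariate_normal(X, m0, rho = 0.5, seed = 7)
  expect_equal(cor(Yr[, 1], Yr[, 2]), 0.5, tolerance = 3 * se / (1 - 0.5^2))

  # cell-conditional mean difference tracks the table difference
  mx <- penetrance_model("xor", gain = 1, maf = 0.4)
  Yx <- phenotypes_bivariate_normal(X, mx, rho = 0, seed = 8)
  cell_low <- X[, 1] == 0 & X[, 2] == 0   # f = 1
  cell_high <- X[, 1] == 0 & X[, 2] == 1  # f = 2
  expect_equal(mean(Yx[cell_high, 1]) - mean(Yx[cell_low, 1]), 1,
               tolerance = 0.05)
})

test_that("copula gamma phenotypes match gamma moments and copula rank correlation", {
  n <- 50000
  X <- simulate_genotypes(n, 2, maf = 0.2, seed = 10)
  m0 <- penetrance_model("null", base = 0.5)   # shape 0.25, scale 2
  Y <- phenotypes_bivariate_gamma(X, m0, rho = 0, seed = 11)
  expect_equal(mean(Y[, 1]), 0.5, tolerance = 3 / sqrt(n) * 2)
  expect_equal(var(Y[, 1]), 1, tolerance = 0.1)
  skew <- mean((Y[, 1] - mean(Y[, 1]))^3) / sd(Y[, 1])^3
  expect_equal(skew, 2 / 0.5, tolerance = 0.35)  # skewness 2/f
  expect_lt(abs(cor(Y[, 1], Y[, 2])), 3 / sqrt(n) * 1.5)

  # Gaussian-copula Spearman correlation: (6/pi) asin(rho/2)
  Yr <- phenotypes_bivariate_gamma(X, m0, rho = 0.5, seed = 12)
  rs <- cor(Yr[, 1], Yr[, 2], method = "spearman")
  expect_equal(rs, (6 / pi) * asin(0.25), tolerance = 0.015)

  # nonpositive cell effects are rejected before sampling
  mneg <- penetrance_model("null", base = 1)
  mneg$table[2, 2] <- -0.5
  expect_error(phenotypes_bivariate_gamma(X, mneg, 0, 1), "positive")
})

test_that("whole-dataset simulation is deterministic and flags the causal pair", {
  m <- penetrance_model("xor", maf = 0.2, heritability = 0.3)
  s1 <- simulate_dataset(100, 8, m, "gamma", rho = 0.25, seed = 31)
  s2 <- simulate_dataset(100, 8, m, "gamma", rho = 0.25, seed = 31)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_equal(dim(s1$genotypes), c(100, 8))
  expect_equal(s1$causal_pair, c(1L, 2L))
})

test_that("hit ratio rises with effect size and is computed per method", {
  # tiny design: 5 SNPs, 3 gain levels, method = mqmdr (fast, no clustering)
  gains <- c(0.3, 1.0, 2.5)
  hr <- vapply(gains, function(g) {
    m <- penetrance_model("xor", gain = g, maf = 0.4)
    hit_ratio_experiment(m, methods = "mqmdr", n_datasets = 15, n = 120,
                         p = 5, family = "normal", rho = 0, n_folds = 5,
                         seed = 100)$hit_ratio
  }, numeric(1))
  expect_true(all(diff(hr) >= 0))
  expect_gte(hr[3], 0.9)

  m <- penetrance_model("xor", gain = 2.5, maf = 0.4)
  out <- hit_ratio_experiment(m, methods = c("cmdr", "mqmdr"),
                              n_datasets = 5, n = 120, p = 5,
                              family = "normal", n_folds = 5, seed = 3)
  expect_named(out$hit_ratio, c("cmdr", "mqmdr"))
  expect_equal(dim(out$hits), c(5, 2))
  expect_error(hit_ratio_experiment(m, methods = "bogus", n_datasets = 2),
               "unknown method")
})

test_that("null experiment counts best pairs and both null modes work", {
  out <- null_fpr_experiment(4, n = 80, p = 5, n_folds = 4, seed = 5,
                             n_restarts = 2)
  expect_equal(sum(out$pair_counts), 4)
  expect_equal(out$expected_rate, 1 / choose(5, 2))
  expect_true(out$designated_rate %in% c(0, 0.25, 0.5, 0.75, 1))
  out2 <- null_fpr_experiment(3, n = 80, p = 5, mode = "direct",
                              n_folds = 4, seed = 6, n_restarts = 2)
  expect_equal(sum(out2$pair_counts), 3)
})
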