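# A small retained-sample fixture shared across engine tests: genotypes,
# fuzzy memberships and a train/test split, built in code.
make_engine_fixture <- function(n = 120, p = 6, seed = 21) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(NULL, paste0("SNP", 1:p)))
  m1 <- runif(n, 0.05, 0.95)
  M2 <- cbind(m1, 1 - m1)
  Y <- matrix(rnorm(2 * n), n, 2)
  tr <- sort(sample(n, round(0.75 * n)))
  list(X = X, trimmed = list(retained_index = 1:n, memberships2 = M2),
       Y = Y, split = list(train = tr, test = setdiff(1:n, tr)),
       theta = sum(M2[, 1]) / sum(M2[, 2]))
}

test_that("cell indexing is the mixed-radix-3 bijection", {
  expect_equal(genotype_cell_index(c(0, 0)), 1)
  expect_equal(genotype_cell_index(c(1, 2)), 6)  # 1*3 + 2, 1-based
  expect_equal(genotype_cell_index(c(2, 2)), 9)
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  expect_equal(sort(genotype_cell_index(grid)), 1:27)  # bijective
  expect_error(genotype_cell_index(c(0, 3)), "0, 1 or 2")
})

test_that("cell tables aggregate masses, ratios and labels correctly", {
  fx <- make_engine_fixture()
  ct <- build_cell_table(c(2, 5), fx$split$train, fx$X, fx$trimmed, fx$theta)
  orc <- oracle_cell_table(c(2, 5), fx$split$train, fx$X,
                           fx$trimmed$memberships2, fx$theta)
  expect_equal(ct$mass1, orc$mass1, tolerance = 1e-12)
  expect_equal(ct$mass2, orc$mass2, tolerance = 1e-12)
  expect_equal(ct$label, orc$label)
  # masses conserve the training totals exactly
  expect_equal(sum(ct$mass1), sum(fx$trimmed$memberships2[fx$split$train, 1]))
  expect_equal(sum(ct$mass2), sum(fx$trimmed$memberships2[fx$split$train, 2]))

  # single-sample cell arithmetic, infinity and the tie rule
  X1 <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE)
  trm <- list(retained_index = 1:3,
              memberships2 = rbind(c(0.7, 0.3), c(0.9, 0.0), c(0.5, 0.5)))
  ct1 <- build_cell_table(c(1, 2), 1:3, X1, trm, theta = 1)
  expect_equal(ct1$local_ratio[1], 7 / 3)
  expect_equal(ct1$local_ratio[5], Inf)       # mass2 = 0 -> D1 forced
  expect_equal(ct1$label[5], "D1")
  expect_equal(ct1$label[9], "D1")            # theta_j == theta -> D1
  expect_true(all(ct1$label[ct1$counts == 0] == "D2"))  # empty -> D2
  expect_true(all(is.na(ct1$local_ratio[ct1$counts == 0])))
})

test_that("hotelling_t2 matches the straight-line oracle and the pooled t", {
  set.seed(31)
  for (rep in 1:25) {
    q <- sample(1:3, 1)
    n1 <- sample(4:30, 1); n2 <- sample(4:30, 1)
    Y <- matrix(rnorm((n1 + n2) * q), ncol = q)
    grp <- rep(c("D1", "D2"), c(n1, n2))
    t2 <- hotelling_t2(Y, grp)
    expect_equal(t2, oracle_hotelling_t2(Y, grp), tolerance = 1e-10)
    if (q == 1)
      expect_equal(t2, oracle_pooled_t(Y[, 1], grp)^2, tolerance = 1e-10)
    # invariant to swapping group labels
    expect_equal(t2, hotelling_t2(Y, ifelse(grp == "D1", "D2", "D1")),
                 tolerance = 1e-12)
  }
  # zero mean difference -> T^2 = 0
  sq <- as.matrix(expand.grid(0:1, 0:1))
  Y0 <- rbind(sq, sq)
  expect_equal(hotelling_t2(Y0, rep(c("D1", "D2"), each = 4)), 0)
  # degenerate inputs give NA, not an error
  expect_message(v <- hotelling_t2(matrix(rnorm(8), 4, 2), rep("D1", 4)),
                 "two groups")
  expect_true(is.na(v))
  expect_message(v2 <- hotelling_t2(matrix(rnorm(6), 3, 2),
                                    c("D1", "D2", "D2")), "degrees")
  expect_true(is.na(v2))
})

test_that("evaluate_model labels test cells by training rules and scores both halves", {
  fx <- make_engine_fixture()
  ev <- evaluate_model(c(1, 4), fx$split, fx$X, fx$Y, fx$trimmed, fx$theta)
  # independent recomputation: oracle labels -> oracle T^2
  orc <- oracle_cell_table(c(1, 4), fx$split$train, fx$X,
                           fx$trimmed$memberships2, fx$theta)
  lab <- orc$label[genotype_cell_index(fx$X[, c(1, 4)])]
  expect_equal(ev$t2_train,
               oracle_hotelling_t2(fx$Y[fx$split$train, ],
                                   lab[fx$split$train]), tolerance = 1e-10)
  expect_equal(ev$t2_test,
               oracle_hotelling_t2(fx$Y[fx$split$test, ],
                                   lab[fx$split$test]), tolerance = 1e-10)
  expect_gte(ev$t2_train, 0)
})

test_that("cross_validate is deterministic, exhaustive and ranks by CVC", {
  fx <- make_engine_fixture(n = 150, p = 6)
  cv1 <- cross_validate(fx$X, fx$Y, fx$trimmed, fx$theta, order = 2,
                        n_folds = 5, seed = 9)
  cv2 <- cross_validate(fx$X, fx$Y, fx$trimmed, fx$theta, order = 2,
                        n_folds = 5, seed = 9)
  expect_identical(cv_results(cv1), cv_results(cv2))
  expect_equal(ncol(cv1$combos), choose(6, 2))
  expect_setequal(cv1$ranking, seq_len(choose(6, 2)))
  expect_equal(sum(cv1$cvc), 5)  # one best model per fold
  # ranked output ordered by cvc then mean training T^2
  res <- cv_results(cv1)
  expect_true(all(diff(res$cvc) <= 0))
  # order > p errors; sparse-cells warning fires when 3^order ~ fold size
  expect_error(cross_validate(fx$X, fx$Y, fx$trimmed, fx$theta, order = 7,
                              n_folds = 5, seed = 1), "exceeds")
  expect_warning(cross_validate(fx$X[1:30, ], fx$Y[1:30, ],
                                list(retained_index = 1:30,
                                     memberships2 = fx$trimmed$memberships2[1:30, ]),
                                fx$theta, order = 3, n_folds = 5, seed = 1),
                 "sparse")
})

test_that("the vectorized fold scan agrees with the single-model evaluator", {
  fx <- make_engine_fixture(n = 140, p = 5, seed = 33)
  cv <- cross_validate(fx$X, fx$Y, fx$trimmed, fx$theta, order = 2,
                       n_folds = 4, seed = 17)
  for (f in 1:4) {
    split <- list(train = which(cv$folds_id != f),
                  test = which(cv$folds_id == f))
    for (cand in c(1, 5, 10)) {
      ev <- evaluate_model(cv$combos[, cand], split, fx$X, fx$Y,
                           fx$trimmed, fx$theta)
      expect_equal(cv$t2_train[f, cand], ev$t2_train, tolerance = 1e-9)
      expect_equal(cv$t2_test[f, cand], ev$t2_test, tolerance = 1e-9)
    }
  }
})

test_that("crisp memberships with one trait reduce to the count-ratio QMDR-style rule", {
  set.seed(41)
  n <- 100
  X <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
  y <- rnorm(n)
  crisp <- as.numeric(y > 0)
  trm <- list(retained_index = 1:n, memberships2 = cbind(crisp, 1 - crisp))
  theta <- sum(crisp) / sum(1 - crisp)
  split <- list(train = 1:70, test = 71:100)
  ev <- evaluate_model(c(1, 2), split, X, matrix(y, ncol = 1), trm, theta)
  # independent univariate oracle: count ratio per cell vs global count ratio
  cells <- genotype_cell_index(X[, c(1, 2)])
  lab <- rep("D2", 9)
  for (j in 1:9) {
    idx <- intersect(which(cells == j), split$train)
    if (length(idx) &&
        sum(crisp[idx]) >= theta * sum(1 - crisp[idx])) lab[j] <- "D1"
  }
  g <- lab[cells]
  expect_equal(ev$t2_train, oracle_pooled_t(y[split$train],
                                            g[split$train])^2,
               tolerance = 1e-10)
})

test_that("under the null the selected pair is approximately uniform over candidates", {
  # 3 SNPs -> 3 pairs; with pure-noise phenotypes each pair should win
  # about equally often across seeds
  set.seed(55)
  wins <- integer(3)
  for (r in 1:60) {
    n <- 60
    X <- matrix(rbinom(n * 3, 2, 0.5), n, 3)
    m1 <- runif(n)
    trm <- list(retained_index = 1:n, memberships2 = cbind(m1, 1 - m1))
    Y <- matrix(rnorm(2 * n), n, 2)
    cv <- cross_validate(X, Y, trm, sum(m1) / sum(1 - m1), order = 2,
                         n_folds = 3, seed = r)
    wins[cv$best] <- wins[cv$best] + 1
  }
  expect_gt(chisq.test(wins)$p.value, 0.001)
})

test_that("permutation p-values hit the boundary cases of the indicator sum", {
  # tiny deterministic setup: observed stat forced above / below all nulls
  fx <- make_engine_fixture(n = 60, p = 3, seed = 61)
  cfg <- list(method = "mqmdr", variant = "noise", trait = NULL, order = 2,
              n_folds = 3, fuzzifier = 2, tol = 1e-6, max_iter = 100,
              n_restarts = 2, noise_delta = "auto")
  pt <- permutation_test(fx$X, fx$Y, cfg, B = 5, seed = 3,
                         t2_observed = Inf)
  expect_equal(pt$p_value, 0)  # no null statistic exceeds the observed
  pt2 <- permutation_test(fx$X, fx$Y, cfg, B = 5, seed = 3,
                          t2_observed = -Inf)
  expect_equal(pt2$p_value, 1)  # every null statistic exceeds the observed
  expect_length(pt$t2_null, 5)
  expect_identical(pt$t2_null, pt2$t2_null)  # same seed, same null draws
})
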