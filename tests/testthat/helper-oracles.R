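# Independent straight-line oracles, written with explicit loops and kept
# free of the package's internal code paths.

# Hotelling's two-sample T^2, loop by loop from its definition.
oracle_hotelling_t2 <- function(Y, group) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  lev <- unique(group)
  x1 <- Y[group == lev[1], , drop = FALSE]
  x2 <- Y[group == lev[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2); q <- ncol(Y)
  xbar1 <- numeric(q); xbar2 <- numeric(q)
  for (j in 1:q) {
    for (i in 1:n1) xbar1[j] <- xbar1[j] + x1[i, j] / n1
    for (i in 1:n2) xbar2[j] <- xbar2[j] + x2[i, j] / n2
  }
  S1 <- matrix(0, q, q); S2 <- matrix(0, q, q)
  for (i in 1:n1) S1 <- S1 + tcrossprod(x1[i, ] - xbar1) / (n1 - 1)
  for (i in 1:n2) S2 <- S2 + tcrossprod(x2[i, ] - xbar2) / (n2 - 1)
  Sp <- (n1 - 1) / (n1 + n2 - 2) * S1 + (n2 - 1) / (n1 + n2 - 2) * S2
  d <- xbar1 - xbar2
  drop(t(d) %*% solve((1 / n1 + 1 / n2) * Sp) %*% d)
}

# Pooled-variance two-sample t statistic (textbook form).
oracle_pooled_t <- function(y, group) {
  lev <- unique(group)
  a <- y[group == lev[1]]; b <- y[group == lev[2]]
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Plain two-cluster fuzzy c-means memberships from fixed centers.
oracle_fcm_memberships <- function(Y, centers, m) {
  n <- nrow(Y)
  M <- matrix(0, n, 2)
  for (i in 1:n) {
    d2 <- c(sum((Y[i, ] - centers[1, ])^2), sum((Y[i, ] - centers[2, ])^2))
    for (k in 1:2) {
      M[i, k] <- 1 / sum((d2[k] / d2)^(1 / (m - 1)))
    }
  }
  M
}

# Cell masses, local ratios and labels for one SNP set, by explicit loops.
oracle_cell_table <- function(snp_set, train, X, M2, theta) {
  K <- 3^length(snp_set)
  mass1 <- numeric(K); mass2 <- numeric(K); cnt <- integer(K)
  for (i in train) {
    j <- 1
    for (k in seq_along(snp_set)) {
      j <- (j - 1) * 3 + X[i, snp_set[k]] + 1
    }
    mass1[j] <- mass1[j] + M2[i, 1]
    mass2[j] <- mass2[j] + M2[i, 2]
    cnt[j] <- cnt[j] + 1
  }
  label <- ifelse(cnt > 0 & mass1 >= theta * mass2, "D1", "D2")
  list(mass1 = mass1, mass2 = mass2, counts = cnt, label = label)
}

# Small labeled two-cluster dataset with optional injected outliers.
make_two_clusters <- function(n_per = 100, sep = 10, sd = 1, n_out = 0,
                              out_dist = 20, seed = 1) {
  set.seed(seed)
  Y <- rbind(
    cbind(rnorm(n_per, -sep / 2, sd), rnorm(n_per, 0, sd)),
    cbind(rnorm(n_per, sep / 2, sd), rnorm(n_per, 0, sd)))
  lab <- rep(1:2, each = n_per)
  if (n_out > 0) {
    ang <- runif(n_out, 0, 2 * pi)
    Y <- rbind(Y, cbind(out_dist * cos(ang), out_dist * sin(ang)))
    lab <- c(lab, rep(3, n_out))
  }
  list(Y = Y, labels = lab)
}
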