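# Exhaustive SNP-combination search: per-cell membership-mass ratios,
# D1/D2 labeling against the global ratio, Hotelling's T^2 evaluation under
# N-fold cross-validation with cross-validation consistency (CVC), and
# permutation p-values. The per-fold work is vectorized across all candidate
# SNP sets at once (cell aggregation via grouped sums, T^2 via closed-form
# 1x1 / 2x2 inverses), which is what makes exhaustive order-2 scans and
# large simulation studies tractable in plain R.

#' Multilocus genotype cell index
#'
#' Maps an m-vector of additive genotype codes (0/1/2) to a cell index in
#' \code{1..3^m} by mixed-radix-3 encoding (first SNP most significant).
#' Accepts a vector (one cell) or a matrix (samples in rows).
#'
#' @param genotypes integer vector of length m, or an n x m matrix.
#' @return integer cell index (or vector of indices), 1-based.
#' @export
genotype_cell_index <- function(genotypes) {
  g <- if (is.matrix(genotypes)) genotypes else matrix(genotypes, nrow = 1L)
  if (!all(g %in% c(0L, 1L, 2L)))
    stop_("genotype codes must be 0, 1 or 2")
  m <- ncol(g)
  idx <- rep(0L, nrow(g))
  for (k in seq_len(m)) idx <- idx * 3L + as.integer(g[, k])
  idx + 1L
}

# Grouped sum of vals over integer bins 1..nbins (zero for empty bins).
.groupsum <- function(vals, idx, nbins) {
  s <- rowsum(vals, idx, reorder = FALSE)
  out <- numeric(nbins)
  out[as.integer(rownames(s))] <- s
  out
}

#' Hotelling's two-sample T-squared statistic
#'
#' T^2 = (xbar1 - xbar2)' [(1/n1 + 1/n2) S_pooled]^{-1} (xbar1 - xbar2),
#' with S_pooled the df-weighted pooled sample covariance of the two groups.
#' Used to score the mean separation of the D1 and D2 phenotype groups.
#'
#' @param Y numeric matrix (samples x traits) or vector (one trait).
#' @param group length-n grouping with exactly two levels (e.g. "D1"/"D2",
#'   logical, or 1/2).
#' @return nonnegative scalar; \code{NA} (with a message) when the statistic
#'   is undefined: a group is empty, degrees of freedom are insufficient
#'   (n1 + n2 - 2 < q), or the pooled covariance is singular.
#' @export
hotelling_t2 <- function(Y, group) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1L)
  lev <- unique(group)
  if (length(lev) != 2L) {
    message("hotelling_t2: need exactly two groups; returning NA")
    return(NA_real_)
  }
  g1 <- group == lev[1L]
  n1 <- sum(g1); n2 <- sum(!g1); q <- ncol(Y)
  if (n1 < 1L || n2 < 1L || (n1 + n2 - 2L) < q) {
    message("hotelling_t2: insufficient degrees of freedom; returning NA")
    return(NA_real_)
  }
  x1 <- Y[g1, , drop = FALSE]; x2 <- Y[!g1, , drop = FALSE]
  d <- colMeans(x1) - colMeans(x2)
  Sp <- (crossprod(sweep(x1, 2L, colMeans(x1))) +
         crossprod(sweep(x2, 2L, colMeans(x2)))) / (n1 + n2 - 2L)
  V <- (1 / n1 + 1 / n2) * Sp
  t2 <- tryCatch(drop(crossprod(d, solve(V, d))),
                 error = function(e) NA_real_)
  if (!is.finite(t2) || t2 < 0) {
    message("hotelling_t2: singular pooled covariance; returning NA")
    return(NA_real_)
  }
  t2
}

# Vectorized Hotelling T^2 across candidate models. Ym: n x q phenotypes,
# G: n x ncand logical (TRUE = D1). Returns length-ncand vector with -Inf
# for invalid models (empty group, df < q, singular pooled covariance).
.t2_block <- function(Ym, G) {
  n <- nrow(Ym); q <- ncol(Ym); ncand <- ncol(G)
  out <- rep(-Inf, ncand)
  if (n < 2L) return(out)
  n1 <- colSums(G); n2 <- n - n1
  valid <- n1 >= 1L & n2 >= 1L & (n - 2L) >= q
  if (!any(valid)) return(out)
  Gd <- G + 0                      # numeric for crossprod
  S1 <- crossprod(Gd, Ym)          # ncand x q group-1 trait sums
  Ts <- colSums(Ym)
  m1 <- S1 / n1
  m2 <- sweep(-S1, 2L, Ts, "+") / n2
  d <- m1 - m2
  c0 <- 1 / n1 + 1 / n2
  df <- n - 2L
  if (q == 1L) {
    tot <- sum(Ym[, 1L]^2)
    ss <- tot - n1 * m1[, 1L]^2 - n2 * m2[, 1L]^2
    sp <- ss / df
    t2 <- d[, 1L]^2 / (sp * c0)
    ok <- valid & sp > 1e-300 & is.finite(t2)
    out[ok] <- t2[ok]
  } else if (q == 2L) {
    tot11 <- sum(Ym[, 1L]^2); tot22 <- sum(Ym[, 2L]^2)
    tot12 <- sum(Ym[, 1L] * Ym[, 2L])
    s11 <- (tot11 - n1 * m1[, 1L]^2 - n2 * m2[, 1L]^2) / df
    s22 <- (tot22 - n1 * m1[, 2L]^2 - n2 * m2[, 2L]^2) / df
    s12 <- (tot12 - n1 * m1[, 1L] * m1[, 2L] - n2 * m2[, 1L] * m2[, 2L]) / df
    det <- s11 * s22 - s12^2
    t2 <- (d[, 1L]^2 * s22 - 2 * d[, 1L] * d[, 2L] * s12 +
             d[, 2L]^2 * s11) / (det * c0)
    ok <- valid & det > 1e-300 & is.finite(t2) & t2 >= 0
    out[ok] <- t2[ok]
  } else {
    for (j in which(valid)) {
      gj <- G[, j]
      out[j] <- {
        x1 <- Ym[gj, , drop = FALSE]; x2 <- Ym[!gj, , drop = FALSE]
        dd <- colMeans(x1) - colMeans(x2)
        Sp <- (crossprod(sweep(x1, 2L, colMeans(x1))) +
               crossprod(sweep(x2, 2L, colMeans(x2)))) / df
        t2 <- tryCatch(drop(crossprod(dd, solve(c0[j] * Sp, dd))),
                       error = function(e) -Inf)
        if (is.finite(t2) && t2 >= 0) t2 else -Inf
      }
    }
  }
  out
}

#' Per-cell membership table for one SNP set
#'
#' Aggregates, over a training index, the C1 and C2 membership masses of the
#' samples falling in each of the 3^m multilocus genotype cells, computes
#' the local ratio theta_j = mass1_j / mass2_j, and labels the cell "D1" iff
#' theta_j >= theta (the global ratio). Cells with no training sample are
#' marked empty (local ratio \code{NA}) and labeled "D2"; cells with
#' positive C1 mass but zero C2 mass have local ratio \code{Inf} and are
#' labeled "D1".
#'
#' @param snp_set integer vector of SNP column indices (length m).
#' @param training_index integer positions (within the retained samples)
#'   forming the training set.
#' @param X genotype matrix of the retained samples (n' x p, codes 0/1/2).
#' @param trimmed result of \code{\link{trim_noise}} (provides
#'   \code{memberships2} aligned with the rows of \code{X}).
#' @param theta global ratio from \code{\link{global_ratio}}.
#' @return object of class \code{cell_table}: list with \code{order},
#'   \code{snp_set}, \code{counts}, \code{mass1}, \code{mass2},
#'   \code{local_ratio}, \code{label}.
#' @export
build_cell_table <- function(snp_set, training_index, X, trimmed, theta) {
  m <- length(snp_set)
  K <- 3L^m
  M2 <- trimmed$memberships2
  cells <- genotype_cell_index(X[training_index, snp_set, drop = FALSE])
  counts <- tabulate(cells, nbins = K)
  mass1 <- .groupsum(M2[training_index, 1L], cells, K)
  mass2 <- .groupsum(M2[training_index, 2L], cells, K)
  ratio <- ifelse(counts > 0L, mass1 / mass2, NA_real_)
  label <- ifelse(counts > 0L & mass1 >= theta * mass2, "D1", "D2")
  structure(list(order = m, snp_set = snp_set, counts = counts,
                 mass1 = mass1, mass2 = mass2, local_ratio = ratio,
                 label = label, theta = theta),
            class = "cell_table")
}

#' Train/test T-squared for one SNP set
#'
#' Builds the cell table on the training samples, assigns every sample
#' (train and test) the D1/D2 label of its cell (test cells unseen in
#' training are D2), and computes Hotelling's T^2 separately on the training
#' and test phenotypes.
#'
#' @param snp_set integer vector of SNP indices.
#' @param fold_split list with integer components \code{train} and
#'   \code{test} partitioning the retained samples.
#' @param X,Y_std genotypes and standardized phenotypes of the retained
#'   samples (rows aligned).
#' @param trimmed,theta clustering outputs, as in
#'   \code{\link{build_cell_table}}.
#' @return list with \code{t2_train} and \code{t2_test} (\code{-Inf} marks
#'   an invalid statistic, e.g. all samples in one group).
#' @export
evaluate_model <- function(snp_set, fold_split, X, Y_std, trimmed, theta) {
  ct <- build_cell_table(snp_set, fold_split$train, X, trimmed, theta)
  lab <- ct$label == "D1"
  cells_all <- genotype_cell_index(X[, snp_set, drop = FALSE])
  g <- lab[cells_all]
  t2 <- function(idx) {
    gi <- g[idx]
    if (!any(gi) || all(gi)) return(-Inf)
    .t2_block(Y_std[idx, , drop = FALSE], matrix(gi, ncol = 1L))[1L]
  }
  list(t2_train = t2(fold_split$train), t2_test = t2(fold_split$test))
}

# Fold assignment: sizes differing by at most one, seeded shuffle.
.assign_folds <- function(n, n_folds, seed) {
  with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
}

# First principal component loading of the training-sample covariance of
# standardized traits; sign fixed so the largest-magnitude entry is positive.
.first_pc_loading <- function(Ytr) {
  ev <- eigen(stats::cov(Ytr), symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (ev$values[1L] - ev$values[min(2L, length(ev$values))] < 1e-12)
    warning("leading eigenvalues tied; FPC fixed by the sign rule",
            call. = FALSE)
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

# Shared cross-validated exhaustive search over candidate SNP sets.
#   method "cmdr":  cell D1 iff C1 mass >= theta * C2 mass (theta fixed);
#                   statistic = Hotelling T^2 on all traits.
#   method "qmdr":  cell high iff local trait mean >= global training mean;
#                   statistic = squared pooled t (T^2 with q = 1).
#   method "mqmdr": cell high iff local FPC-score mean >= global training
#                   mean (FPC refit per training fold); statistic = T^2 on
#                   all traits.
# Empty training cells, and test cells unseen in training, are D2/low.
.cv_search <- function(X, Y, folds_id, combos, method,
                       member2 = NULL, theta = NULL, trait = NULL,
                       block_size = 5000L) {
  n <- nrow(X)
  n_folds <- max(folds_id)
  m <- nrow(combos)
  K <- 3L^m
  ncand <- ncol(combos)

  # n x ncand cell indices, built once
  C <- matrix(1L, n, ncand)
  for (k in seq_len(m)) {
    Ck <- X[, combos[k, ], drop = FALSE]
    C <- C + Ck * 3L^(m - k)
  }
  storage.mode(C) <- "integer"

  T2tr <- matrix(NA_real_, n_folds, ncand)
  T2te <- matrix(NA_real_, n_folds, ncand)
  blocks <- split(seq_len(ncand), ceiling(seq_len(ncand) / block_size))

  for (f in seq_len(n_folds)) {
    tr <- which(folds_id != f)
    te <- which(folds_id == f)
    ntr <- length(tr); nte <- length(te)

    if (method == "cmdr") {
      a <- member2[, 1L]
      thr <- theta
      Ystat <- Y
    } else if (method == "qmdr") {
      a <- Y[, trait]
      thr <- mean(a[tr])
      Ystat <- Y[, trait, drop = FALSE]
    } else {  # mqmdr
      v <- .first_pc_loading(Y[tr, , drop = FALSE])
      a <- drop(Y %*% v)
      thr <- mean(a[tr])
      Ystat <- Y
    }
    atr <- a[tr]

    for (J in blocks) {
      nb <- length(J)
      nbins <- K * nb
      offs <- rep((seq_len(nb) - 1L) * K, each = ntr)
      idx_tr <- as.vector(C[tr, J, drop = FALSE]) + offs
      cnt <- tabulate(idx_tr, nbins = nbins)
      Asum <- .groupsum(rep(atr, nb), idx_tr, nbins)
      Bsum <- if (method == "cmdr") cnt - Asum else cnt
      lab <- cnt > 0L & (Asum >= thr * Bsum)
      Gtr <- matrix(lab[idx_tr], ntr, nb)
      idx_te <- as.vector(C[te, J, drop = FALSE]) +
        rep((seq_len(nb) - 1L) * K, each = nte)
      Gte <- matrix(lab[idx_te], nte, nb)
      T2tr[f, J] <- .t2_block(Ystat[tr, , drop = FALSE], Gtr)
      T2te[f, J] <- .t2_block(Ystat[te, , drop = FALSE], Gte)
    }
  }

  # CVC: per fold, the best training model (ties -> lexicographically
  # smallest SNP set, i.e. lowest candidate index since combn enumerates
  # lexicographically)
  best_per_fold <- apply(T2tr, 1L, function(z) {
    if (all(!is.finite(z))) NA_integer_ else which.max(z)
  })
  cvc <- tabulate(best_per_fold[!is.na(best_per_fold)], nbins = ncand)

  mean_finite <- function(M) {
    apply(M, 2L, function(z) {
      z <- z[is.finite(z)]
      if (length(z)) mean(z) else NA_real_
    })
  }
  t2_train_mean <- mean_finite(T2tr)
  t2_test_mean <- mean_finite(T2te)

  rank_key <- ifelse(is.na(t2_train_mean), -Inf, t2_train_mean)
  ord <- order(-cvc, -rank_key, seq_len(ncand))

  list(combos = combos, cvc = cvc,
       t2_train = T2tr, t2_test = T2te,
       t2_train_mean = t2_train_mean, t2_test_mean = t2_test_mean,
       ranking = ord, best = ord[1L], folds_id = folds_id,
       n_folds = n_folds, method = method)
}

# Candidate SNP-set enumeration (lexicographic), optionally restricted.
.enumerate_combos <- function(p, order, snp_subset = NULL) {
  pool <- if (is.null(snp_subset)) seq_len(p) else sort(unique(snp_subset))
  if (order > length(pool))
    stop_("interaction order (%d) exceeds the number of SNPs (%d)",
          order, length(pool))
  utils::combn(pool, order)
}

#' Cross-validated exhaustive SNP-set search (multi-CMDR core)
#'
#' Enumerates all order-m SNP sets, and for each CV fold labels the 3^m
#' genotype cells D1/D2 by comparing the per-cell membership-mass ratio with
#' the global ratio theta, scores candidates by Hotelling's T^2 on the
#' training samples, and tallies cross-validation consistency (CVC): the
#' number of folds in which a SNP set is the best training model. The final
#' best model maximizes CVC, with ties broken by larger mean training T^2,
#' then lexicographically.
#'
#' @param X genotype matrix of the retained samples (n' x p).
#' @param Y_std standardized phenotypes of the retained samples (n' x q).
#' @param trimmed,theta outputs of \code{\link{trim_noise}} and
#'   \code{\link{global_ratio}}.
#' @param order interaction order m >= 1.
#' @param n_folds number of CV folds (>= 2).
#' @param seed integer seed driving the fold assignment.
#' @param snp_subset optional integer vector restricting the SNP pool.
#' @return object of class \code{cmdr_cv}; see \code{\link{cv_results}} for
#'   the ranked table. Contains per-fold train/test T^2 for every candidate,
#'   the CVC vector, and the fold assignment.
#' @export
cross_validate <- function(X, Y_std, trimmed, theta, order = 2L,
                           n_folds = 10L, seed = 1L, snp_subset = NULL) {
  if (n_folds < 2L) stop_("n_folds must be at least 2")
  if (order < 1L) stop_("order must be at least 1")
  n <- nrow(X)
  combos <- .enumerate_combos(ncol(X), order, snp_subset)
  if (3L^order >= floor(n * (n_folds - 1) / n_folds))
    warning(sprintf(
      "3^%d cells vs ~%d training samples: expect sparse cells",
      order, floor(n * (n_folds - 1) / n_folds)), call. = FALSE)
  folds_id <- .assign_folds(n, n_folds, seed)
  res <- .cv_search(X, Y_std, folds_id, combos, "cmdr",
                    member2 = trimmed$memberships2, theta = theta)
  res$snp_ids <- colnames(X)
  res$seed <- seed
  class(res) <- "cmdr_cv"
  res
}

#' Ranked model table from a cross-validated search
#'
#' @param fit a \code{cmdr_cv} object.
#' @param top number of models to return (default all).
#' @return data.frame with columns \code{snp_set}, \code{cvc},
#'   \code{t2_train_mean}, \code{t2_test_mean}, ranked by CVC then mean
#'   training T^2.
#' @export
cv_results <- function(fit, top = Inf) {
  ord <- fit$ranking
  if (is.finite(top)) ord <- ord[seq_len(min(top, length(ord)))]
  ids <- fit$snp_ids
  nm <- apply(fit$combos[, ord, drop = FALSE], 2L, function(s) {
    paste(if (is.null(ids)) paste0("SNP", s) else ids[s], collapse = ",")
  })
  data.frame(snp_set = nm,
             cvc = fit$cvc[ord],
             t2_train_mean = fit$t2_train_mean[ord],
             t2_test_mean = fit$t2_test_mean[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cmdr_cv <- function(x, ...) {
  cat(sprintf("Cross-validated %s search: %d candidate SNP sets, %d folds\n",
              x$method, ncol(x$combos), x$n_folds))
  print(utils::head(cv_results(x), 5L))
  invisible(x)
}
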