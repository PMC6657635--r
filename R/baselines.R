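# Comparison methods sharing the CV/CVC machinery with the multi-CMDR
# engine: univariate QMDR (local vs global trait mean, squared pooled t)
# and multi-QMDR with first-principal-component cell labeling (Hotelling's
# T^2). Full searches run through multicmdr(method = "qmdr" | "mqmdr");
# the functions here evaluate a single SNP set on one train/test split.

# Shared single-model evaluator: label cells by mean of `score` vs the
# global training mean, then compute T^2 on `Ystat` for train and test.
.mean_rule_evaluate <- function(snp_set, fold_split, X, score, Ystat) {
  m <- length(snp_set)
  K <- 3L^m
  tr <- fold_split$train
  cells_all <- genotype_cell_index(X[, snp_set, drop = FALSE])
  cnt <- tabulate(cells_all[tr], nbins = K)
  ssum <- .groupsum(score[tr], cells_all[tr], K)
  thr <- mean(score[tr])
  lab <- cnt > 0L & (ssum >= thr * cnt)   # empty / unseen cells -> low risk
  g <- lab[cells_all]
  t2 <- function(idx) {
    gi <- g[idx]
    if (!any(gi) || all(gi)) return(-Inf)
    .t2_block(Ystat[idx, , drop = FALSE], matrix(gi, ncol = 1L))[1L]
  }
  list(t2_train = t2(fold_split$train), t2_test = t2(fold_split$test))
}

#' QMDR evaluation of one SNP set
#'
#' Univariate QMDR on a single standardized trait: a genotype cell is
#' high-risk iff its local trait mean is greater than or equal to the global
#' mean of the training samples; the model score is the squared
#' pooled-variance two-sample t statistic between the high- and low-risk
#' groups (equivalently Hotelling's T^2 with q = 1). Empty training cells
#' and test cells unseen in training are low-risk.
#'
#' @param snp_set integer vector of SNP indices.
#' @param fold_split list with \code{train} and \code{test} index vectors.
#' @param y standardized trait vector (length n).
#' @param X genotype matrix (n x p).
#' @return list with \code{t2_train} and \code{t2_test}; \code{-Inf} marks a
#'   degenerate split (all samples in one risk group).
#' @export
qmdr_evaluate <- function(snp_set, fold_split, y, X) {
  y <- as.numeric(y)
  .mean_rule_evaluate(snp_set, fold_split, X, y, matrix(y, ncol = 1L))
}

#' First-principal-component scores
#'
#' Computes the leading eigenvector of the covariance of the standardized
#' traits over the training samples (sign fixed so that its
#' largest-magnitude entry is positive) and projects every sample onto it.
#' multi-QMDR uses these scores to label genotype cells high/low risk.
#'
#' @param Y_std standardized phenotype matrix (all samples, n x q, q >= 2).
#' @param training_index rows used to estimate the loading.
#' @return list with \code{loading} (length q) and \code{scores} (length n).
#' @export
first_pc_scores <- function(Y_std, training_index = seq_len(nrow(Y_std))) {
  Y_std <- as_matrix_named(Y_std, "phenotype matrix")
  if (ncol(Y_std) < 2L) stop_("first_pc_scores needs at least 2 traits")
  v <- .first_pc_loading(Y_std[training_index, , drop = FALSE])
  list(loading = v, scores = drop(Y_std %*% v))
}

#' Multi-QMDR (FPC) evaluation of one SNP set
#'
#' Labels each genotype cell high-risk iff the local mean of the
#' first-principal-component score (loading estimated on the training
#' samples) is at least the global training mean, then scores the model by
#' Hotelling's T^2 between the two groups on the full multivariate
#' phenotypes. With a single trait this reduces exactly to
#' \code{\link{qmdr_evaluate}}.
#'
#' @param snp_set integer vector of SNP indices.
#' @param fold_split list with \code{train} and \code{test} index vectors.
#' @param Y_std standardized phenotype matrix (n x q).
#' @param X genotype matrix (n x p).
#' @return list with \code{t2_train} and \code{t2_test}.
#' @export
multi_qmdr_evaluate <- function(snp_set, fold_split, Y_std, X) {
  Y_std <- as_matrix_named(Y_std, "phenotype matrix")
  score <- if (ncol(Y_std) == 1L) Y_std[, 1L]
           else first_pc_scores(Y_std, fold_split$train)$scores
  .mean_rule_evaluate(snp_set, fold_split, X, score, Y_std)
}
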