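# End-to-end multi-CMDR pipeline: standardize -> cluster (noise FCM, or a
# no-trim / hard k-means variant) -> trim -> global ratio -> exhaustive CV
# search -> optional permutation p-value. The baselines (QMDR, FPC
# multi-QMDR) plug into the same search through method dispatch.

# Clustering stage for the cmdr method and its two variants. Returns the
# retained-sample index, the n' x 2 membership matrix and the global ratio.
#   "noise":  noise-cluster fuzzy c-means, then trimming (the default).
#   "notrim": plain two-cluster fuzzy c-means, nobody trimmed.
#   "kmeans": hard k-means, crisp 0/1 memberships, nobody trimmed.
.cmdr_prepare <- function(Y_std, variant, fuzzifier, noise_delta, seed,
                          tol, max_iter, n_restarts) {
  if (variant == "noise") {
    delta <- if (identical(noise_delta, "auto")) NULL else noise_delta
    model <- fit_noise_fcm(Y_std, m = fuzzifier, delta = delta, seed = seed,
                           tol = tol, max_iter = max_iter,
                           n_restarts = n_restarts)
    trimmed <- trim_noise(model, Y_std)
  } else if (variant == "notrim") {
    model <- .fit_fcm_core(Y_std, fuzzifier, Inf, seed, tol, max_iter,
                           n_restarts)
    trimmed <- list(retained_index = seq_len(nrow(Y_std)),
                    memberships2 = model$memberships[, 1:2, drop = FALSE])
  } else if (variant == "kmeans") {
    km <- with_seed(seed, stats::kmeans(Y_std, centers = 2L,
                                        nstart = n_restarts))
    M2 <- cbind(as.numeric(km$cluster == 1L), as.numeric(km$cluster == 2L))
    model <- km
    trimmed <- list(retained_index = seq_len(nrow(Y_std)),
                    memberships2 = M2)
  } else stop_("unknown clustering variant '%s'", variant)
  if (any(colSums(trimmed$memberships2) == 0))
    stop_("a cluster has zero total membership mass")
  list(model = model, trimmed = trimmed,
       theta = global_ratio(trimmed))
}

#' Run a full gene-gene interaction analysis
#'
#' The complete pipeline for one dataset: standardize the phenotypes, (for
#' method \code{"cmdr"}) fit the noise-cluster fuzzy c-means, trim noise
#' samples and compute the global ratio, then run the exhaustive
#' cross-validated SNP-set search, and optionally attach a permutation
#' p-value for the final best model.
#'
#' Methods:
#' \describe{
#'   \item{\code{cmdr}}{multi-CMDR: membership-ratio cell labeling,
#'     Hotelling's T^2 on all traits. \code{variant} selects the clustering
#'     flavor: \code{"noise"} (trimmed, default), \code{"notrim"} (fuzzy
#'     c-means without the noise cluster), \code{"kmeans"} (hard k-means,
#'     crisp memberships).}
#'   \item{\code{qmdr}}{univariate QMDR on the trait selected by
#'     \code{trait}: cells high-risk iff the local trait mean is at least
#'     the global training mean; squared pooled-t statistic.}
#'   \item{\code{mqmdr}}{multi-QMDR: cells labeled by first-principal-
#'     component score means (FPC refit on each training fold); Hotelling's
#'     T^2 on all traits.}
#' }
#'
#' @param X genotype matrix (n x p, additive codes 0/1/2), sample rows
#'   aligned with \code{Y}.
#' @param Y quantitative phenotype matrix (n x q), raw scale.
#' @param method one of \code{"cmdr"}, \code{"qmdr"}, \code{"mqmdr"}.
#' @param variant clustering variant for \code{method = "cmdr"}.
#' @param trait trait column (index or name) for \code{method = "qmdr"}.
#' @param order interaction order (default 2).
#' @param n_folds CV folds (default 10).
#' @param B number of permutations for the empirical p-value (0 = skip).
#' @param seed master seed: drives clustering restarts, fold assignment and
#'   permutations; identical seeds give identical results.
#' @param fuzzifier,tol,max_iter,n_restarts,noise_delta clustering options;
#'   \code{noise_delta = "auto"} uses \code{\link{compute_noise_delta}}.
#' @param snp_subset optional integer vector restricting the SNP pool.
#' @return object of class \code{multicmdr_fit}: the \code{cmdr_cv} search
#'   augmented with \code{best_snp_set}, \code{t2_test_best}, clustering
#'   outputs, the configuration, and (if \code{B > 0}) \code{p_value} and
#'   \code{t2_null}.
#' @examples
#' sim <- simulate_dataset(n = 120, p = 5,
#'                         model = penetrance_model("xor", gain = 2),
#'                         family = "normal", rho = 0, seed = 7)
#' fit <- multicmdr(sim$genotypes, sim$phenotypes, n_folds = 5, seed = 7)
#' fit$best_snp_set
#' @export
multicmdr <- function(X, Y, method = c("cmdr", "qmdr", "mqmdr"),
                      variant = c("noise", "notrim", "kmeans"),
                      trait = NULL, order = 2L, n_folds = 10L, B = 0L,
                      seed = 1L, fuzzifier = 2, tol = 1e-6,
                      max_iter = 300L, n_restarts = 5L,
                      noise_delta = "auto", snp_subset = NULL) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  X <- as_matrix_named(X, "genotype matrix")
  if (!all(X %in% c(0, 1, 2))) stop_("genotype codes must be 0, 1 or 2")
  storage.mode(X) <- "integer"
  Y <- as_matrix_named(Y, "phenotype matrix")
  if (nrow(X) != nrow(Y)) stop_("genotype and phenotype sample counts differ")

  Y_std <- standardize_phenotypes(Y)

  if (method == "cmdr") {
    prep <- .cmdr_prepare(Y_std, variant, fuzzifier, noise_delta, seed,
                          tol, max_iter, n_restarts)
    keep <- prep$trimmed$retained_index
    Xr <- X[keep, , drop = FALSE]
    Yr <- Y_std[keep, , drop = FALSE]
    if (n_folds < 2L) stop_("n_folds must be at least 2")
    combos <- .enumerate_combos(ncol(Xr), order, snp_subset)
    folds_id <- .assign_folds(nrow(Xr), n_folds, seed)
    res <- .cv_search(Xr, Yr, folds_id, combos, "cmdr",
                      member2 = prep$trimmed$memberships2,
                      theta = prep$theta)
    res$cluster_model <- prep$model
    res$trimmed <- prep$trimmed
    res$theta <- prep$theta
  } else {
    if (method == "qmdr") {
      if (is.null(trait)) stop_("method 'qmdr' requires a trait")
      if (is.character(trait)) {
        trait <- match(trait, colnames(Y))
        if (is.na(trait)) stop_("trait name not found in phenotype columns")
      }
    } else if (ncol(Y) < 2L) stop_("method 'mqmdr' requires at least 2 traits")
    combos <- .enumerate_combos(ncol(X), order, snp_subset)
    folds_id <- .assign_folds(nrow(X), n_folds, seed)
    res <- .cv_search(X, Y_std, folds_id, combos, method, trait = trait)
  }

  res$snp_ids <- colnames(X)
  res$seed <- seed
  res$config <- list(method = method, variant = variant, trait = trait,
                     order = order, n_folds = n_folds, B = B, seed = seed,
                     fuzzifier = fuzzifier, tol = tol, max_iter = max_iter,
                     n_restarts = n_restarts, noise_delta = noise_delta)
  best <- res$best
  res$best_snp_set <- res$combos[, best]
  res$t2_test_best <- res$t2_test_mean[best]
  class(res) <- c("multicmdr_fit", "cmdr_cv")

  if (B > 0L) {
    pt <- permutation_test(X, Y, config = res$config, B = B, seed = seed,
                           t2_observed = res$t2_test_best)
    res$p_value <- pt$p_value
    res$t2_null <- pt$t2_null
  }
  res
}

#' Permutation test for the final best model
#'
#' Generates \code{B} permuted datasets by shuffling whole phenotype rows
#' across individuals (genotypes fixed), which severs the genotype-phenotype
#' association while preserving the correlation among traits. Each permuted
#' dataset is re-analyzed with the full pipeline (standardization,
#' clustering, trimming, global ratio, CV search) under the same
#' configuration, and its final best model's averaged test T^2 enters the
#' null distribution. The empirical p-value is the fraction of null
#' statistics strictly exceeding the observed one.
#'
#' @param X,Y genotype and raw phenotype matrices.
#' @param config configuration list as stored in a \code{multicmdr_fit}
#'   (fields method, variant, trait, order, n_folds, fuzzifier, tol,
#'   max_iter, n_restarts, noise_delta).
#' @param B number of permutations (>= 1).
#' @param seed seed for the permutation draws.
#' @param t2_observed observed averaged test T^2; if \code{NULL} it is
#'   computed by running the pipeline on the unpermuted data.
#' @return list with \code{p_value}, \code{t2_observed} and the length-B
#'   vector \code{t2_null}.
#' @export
permutation_test <- function(X, Y, config, B = 99L, seed = 1L,
                             t2_observed = NULL) {
  if (B < 1L) stop_("B must be at least 1")
  Y <- as_matrix_named(Y, "phenotype matrix")
  run1 <- function(Yb) {
    fit <- multicmdr(X, Yb, method = config$method,
                     variant = if (is.null(config$variant)) "noise"
                               else config$variant,
                     trait = config$trait, order = config$order,
                     n_folds = config$n_folds, B = 0L, seed = seed,
                     fuzzifier = config$fuzzifier, tol = config$tol,
                     max_iter = config$max_iter,
                     n_restarts = config$n_restarts,
                     noise_delta = config$noise_delta)
    fit$t2_test_best
  }
  if (is.null(t2_observed)) t2_observed <- run1(Y)
  perm_seeds <- derive_seeds(seed, B)
  t2_null <- vapply(seq_len(B), function(b) {
    perm <- with_seed(perm_seeds[b], sample.int(nrow(Y)))
    run1(Y[perm, , drop = FALSE])
  }, numeric(1))
  list(p_value = mean(t2_null > t2_observed, na.rm = FALSE),
       t2_observed = t2_observed, t2_null = t2_null)
}

#' @export
print.multicmdr_fit <- function(x, ...) {
  cfg <- x$config
  ids <- x$snp_ids
  best <- if (is.null(ids)) paste0("SNP", x$best_snp_set) else ids[x$best_snp_set]
  cat(sprintf("multi-CMDR fit (method %s, order %d, %d-fold CV)\n",
              cfg$method, cfg$order, cfg$n_folds))
  if (!is.null(x$theta))
    cat(sprintf("  retained %d samples; global ratio theta = %.4f\n",
                nrow(x$trimmed$memberships2), x$theta))
  cat(sprintf("  best model: %s  (CVC %d/%d, test T^2 = %.4f%s)\n",
              paste(best, collapse = ","), x$cvc[x$best], cfg$n_folds,
              x$t2_test_best,
              if (!is.null(x$p_value))
                sprintf(", permutation p = %.4g", x$p_value) else ""))
  invisible(x)
}
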