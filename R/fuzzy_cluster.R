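# Phenotype standardization and noise-cluster fuzzy c-means (the clustering
# stage of multi-CMDR): two "good" clusters C1/C2 plus a virtual noise
# cluster at constant distance that absorbs outliers, followed by trimming
# and the global membership-mass ratio theta.

#' Standardize quantitative phenotypes
#'
#' Centers and scales each trait column to mean zero and unit sample
#' standard deviation (denominator \code{n - 1}). All downstream analysis
#' operates on standardized phenotypes so that traits measured on different
#' scales contribute comparably to the clustering distance.
#'
#' @param Y numeric matrix, samples in rows, traits in columns. Row names
#'   (sample IDs) and column names (trait names) are preserved.
#' @return numeric matrix of the same shape with each column standardized.
#' @examples
#' Y <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
#' colMeans(standardize_phenotypes(Y))
#' @export
standardize_phenotypes <- function(Y) {
  Y <- as_matrix_named(Y, "phenotype matrix")
  if (nrow(Y) < 2L) stop_("need at least 2 samples to standardize")
  if (any(!is.finite(Y))) stop_("phenotype matrix contains non-finite values")
  mu <- colMeans(Y)
  sdv <- apply(Y, 2L, stats::sd)
  bad <- which(sdv <= 0 | !is.finite(sdv))
  if (length(bad)) {
    nm <- colnames(Y)[bad]
    if (is.null(nm)) nm <- paste0("trait ", bad)
    stop_("constant trait (zero variance): %s", paste(nm, collapse = ", "))
  }
  Ys <- sweep(sweep(Y, 2L, mu, "-"), 2L, sdv, "/")
  dimnames(Ys) <- dimnames(Y)
  Ys
}

#' Noise-cluster distance threshold
#'
#' The noise cluster sits at a constant (virtual) distance from every
#' sample; its threshold delta is set to the average squared Euclidean
#' distance between samples, computed over all \code{n(n-1)/2} unordered
#' pairs. For q standardized independent traits this is approximately 2q.
#'
#' @param Y_std standardized phenotype matrix (samples x traits).
#' @return positive scalar delta (squared-distance units).
#' @export
compute_noise_delta <- function(Y_std) {
  Y_std <- as_matrix_named(Y_std, "phenotype matrix")
  if (nrow(Y_std) < 2L) stop_("need at least 2 samples to compute delta")
  d2 <- stats::dist(Y_std)^2
  delta <- mean(d2)
  if (delta <= 0)
    stop_("all samples identical: delta = 0 degenerates the noise objective")
  delta
}

# One run of alternating optimization of the noise-clustering objective
#   J = sum_i sum_{k=1,2} M_ik^m ||x_i - c_k||^2 + sum_i delta M_i3^m
# where delta (squared-distance units) is the constant squared distance of
# every sample to the virtual noise prototype. Membership update (given
# centers), with d2 denoting squared Euclidean distances:
#   M_ik = d2_ik^{-1/(m-1)} / (sum_j d2_ij^{-1/(m-1)} + delta^{-1/(m-1)})
# delta = Inf drops the noise cluster and reduces to plain two-cluster
# fuzzy c-means.
.fcm_noise_once <- function(Y, m, delta, tol, max_iter, centers0) {
  n <- nrow(Y)
  ex <- -1 / (m - 1)                      # exponent applied to squared dists
  wn <- if (is.finite(delta)) delta^ex else 0
  centers <- centers0
  M <- matrix(0, n, 3L)
  trace <- numeric(max_iter)
  converged <- FALSE

  memb_update <- function(D2) {
    W <- unname(cbind(D2^ex, wn))
    M <- W / rowSums(W)
    zero <- which(D2 <= 1e-300, arr.ind = TRUE)  # sample on a center
    if (nrow(zero)) {
      for (r in unique(zero[, 1L])) {
        M[r, ] <- 0
        M[r, zero[zero[, 1L] == r, 2L][1L]] <- 1 # nearest coincident center
      }
    }
    M
  }
  yss <- rowSums(Y^2)
  sq_dists <- function(centers) {
    # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, clamped against roundoff
    pmax(yss - 2 * Y %*% t(centers) +
           rep(rowSums(centers^2), each = n), 0)
  }

  D2 <- sq_dists(centers)
  for (it in seq_len(max_iter)) {
    M_new <- memb_update(D2)
    Wm <- M_new[, 1:2]^m
    denom <- colSums(Wm)
    if (any(denom == 0)) return(list(collapsed = TRUE))
    centers <- crossprod(Wm, Y) / denom
    if (sum((centers[1L, ] - centers[2L, ])^2) < 1e-12)
      return(list(collapsed = TRUE))
    D2 <- sq_dists(centers)
    J <- sum(Wm * D2) +
      (if (is.finite(delta)) delta * sum(M_new[, 3L]^m) else 0)
    trace[it] <- J
    if (it > 1L && max(abs(M_new - M)) < tol) {
      M <- M_new
      converged <- TRUE
      break
    }
    M <- M_new
  }
  trace <- trace[seq_len(it)]
  list(collapsed = FALSE, centers = centers, memberships = M,
       objective_trace = trace, converged = converged)
}

# k-means++-style draw of two distinct initial centers.
.init_centers <- function(Y) {
  n <- nrow(Y)
  i1 <- sample.int(n, 1L)
  d2 <- rowSums(sweep(Y, 2L, Y[i1, ], "-")^2)
  if (all(d2 == 0)) stop_("all samples identical: cannot initialize centers")
  i2 <- sample.int(n, 1L, prob = d2)
  Y[c(i1, i2), , drop = FALSE]
}

#' Fit fuzzy c-means with a noise cluster
#'
#' Partitions standardized phenotypes into two fuzzy clusters plus a noise
#' cluster by alternating optimization of the noise-clustering objective
#' J_Noise. The noise cluster is a virtual prototype at constant squared
#' distance \code{delta} from every sample, so samples whose squared
#' distance to both cluster centers exceeds \code{delta} accumulate noise
#' membership instead of distorting the centers. The best of
#' \code{n_restarts} seeded restarts (lowest final objective) is returned.
#'
#' @param Y_std standardized phenotype matrix (n x q), n >= 3.
#' @param m fuzzifier exponent, > 1 (default 2).
#' @param delta noise distance threshold; \code{NULL} (default) computes it
#'   with \code{\link{compute_noise_delta}}.
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param tol convergence tolerance on the max absolute membership change.
#' @param max_iter maximum alternating-optimization iterations per restart.
#' @param n_restarts number of random restarts.
#' @return an object of class \code{noise_fcm}: list with \code{centers}
#'   (2 x q), \code{memberships} (n x 3; columns C1, C2, noise; rows sum to
#'   1), \code{delta}, \code{fuzzifier}, \code{objective_trace},
#'   \code{converged}, \code{seed}.
#' @export
fit_noise_fcm <- function(Y_std, m = 2, delta = NULL, seed = 1L,
                          tol = 1e-6, max_iter = 300L, n_restarts = 5L) {
  Y_std <- as_matrix_named(Y_std, "phenotype matrix")
  if (m <= 1) stop_("fuzzifier m must be > 1")
  if (nrow(Y_std) < 3L) stop_("need at least 3 samples to cluster")
  if (is.null(delta)) delta <- compute_noise_delta(Y_std)
  if (!is.finite(delta) || delta <= 0) stop_("delta must be a positive number")
  .fit_fcm_core(Y_std, m, delta, seed, tol, max_iter, n_restarts)
}

# Restart loop shared by fit_noise_fcm (finite delta) and the no-trim
# variant (delta = Inf, i.e. plain two-cluster fuzzy c-means).
.fit_fcm_core <- function(Y_std, m, delta, seed, tol, max_iter, n_restarts) {
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers0 <- .init_centers(Y_std)
      fit <- .fcm_noise_once(Y_std, m, delta, tol, max_iter, centers0)
      if (fit$collapsed) next
      J <- fit$objective_trace[length(fit$objective_trace)]
      if (is.null(best) || J < best$objective_trace[length(best$objective_trace)])
        best <- fit
    }
  })
  if (is.null(best))
    stop_("cluster collapse in every restart: data may have a single cluster")
  structure(
    list(centers = best$centers, memberships = best$memberships,
         delta = delta, fuzzifier = m,
         objective_trace = best$objective_trace,
         converged = best$converged, seed = seed),
    class = "noise_fcm")
}

#' @export
print.noise_fcm <- function(x, ...) {
  n <- nrow(x$memberships)
  hard <- max.col(x$memberships)
  cat("Noise-cluster fuzzy c-means fit\n")
  cat(sprintf("  samples: %d   traits: %d   fuzzifier m = %g   delta = %.4g\n",
              n, ncol(x$centers), x$fuzzifier, x$delta))
  cat(sprintf("  hard sizes: C1 = %d, C2 = %d, noise = %d\n",
              sum(hard == 1L), sum(hard == 2L), sum(hard == 3L)))
  cat(sprintf("  final J_Noise = %.6g (%s after %d iterations)\n",
              x$objective_trace[length(x$objective_trace)],
              if (x$converged) "converged" else "NOT converged",
              length(x$objective_trace)))
  invisible(x)
}

# Standard two-cluster fuzzy memberships from fixed centers:
#   M_ik = 1 / sum_j (d_ik^2 / d_ij^2)^{1/(m-1)}
.two_cluster_memberships <- function(Y, centers, m) {
  D2 <- cbind(rowSums(sweep(Y, 2L, centers[1L, ], "-")^2),
              rowSums(sweep(Y, 2L, centers[2L, ], "-")^2))
  W <- D2^(-1 / (m - 1))
  M <- W / rowSums(W)
  zero <- which(D2 <= 1e-300, arr.ind = TRUE)
  if (nrow(zero)) {
    for (r in unique(zero[, 1L])) {
      M[r, ] <- 0
      M[r, zero[zero[, 1L] == r, 2L][1L]] <- 1
    }
  }
  M
}

#' Trim noise-cluster samples and recompute two-cluster memberships
#'
#' A sample is removed iff its noise membership is the strict maximum of its
#' membership row (hard assignment to noise); ties with a good cluster keep
#' the sample. Retained samples get fresh two-cluster memberships computed
#' from the fitted centers by the standard fuzzy c-means rule, so each row
#' sums to one.
#'
#' @param model a \code{noise_fcm} fit.
#' @param Y_std the standardized phenotype matrix the model was fitted on.
#' @return list with \code{retained_index} (positions of kept samples) and
#'   \code{memberships2} (n' x 2 matrix over C1, C2).
#' @export
trim_noise <- function(model, Y_std) {
  stopifnot(inherits(model, "noise_fcm"))
  Y_std <- as_matrix_named(Y_std, "phenotype matrix")
  M <- model$memberships
  if (nrow(Y_std) != nrow(M)) stop_("Y_std does not match the fitted model")
  noise_max <- M[, 3L] > M[, 1L] & M[, 3L] > M[, 2L]
  retained <- which(!noise_max)
  if (length(retained) < 2L) stop_("fewer than 2 samples retained after trimming")
  M2 <- .two_cluster_memberships(Y_std[retained, , drop = FALSE],
                                 model$centers, model$fuzzifier)
  if (any(colSums(M2) == 0)) stop_("a cluster has zero total membership mass")
  list(retained_index = retained, memberships2 = M2)
}

#' Global membership-mass ratio
#'
#' The ratio theta of the total C1 membership mass to the total C2 mass over
#' the retained samples. Per-cell local ratios are later compared against
#' theta to label multilocus genotype cells.
#'
#' @param trimmed result of \code{\link{trim_noise}} (or any list with a
#'   two-column \code{memberships2} matrix).
#' @return positive scalar theta.
#' @export
global_ratio <- function(trimmed) {
  M2 <- trimmed$memberships2
  s1 <- sum(M2[, 1L]); s2 <- sum(M2[, 2L])
  if (s2 <= 0) stop_("total C2 membership mass is zero")
  s1 / s2
}
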