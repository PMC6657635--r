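# Simulation designs for evaluating interaction detection: Hardy-Weinberg
# genotypes at given minor allele frequencies, a causal SNP pair acting
# through a 3x3 penetrance table, and phenotypes drawn either from a
# bivariate normal around the cell effect or from gamma marginals coupled by
# a Gaussian copula (unit variance in both families, correlation rho).

#' Parameterized 3x3 penetrance tables
#'
#' Builds a penetrance table f[i, j] giving the expected phenotype effect
#' for causal genotype cell (i-1, j-1). Three shapes are provided:
#' \describe{
#'   \item{\code{null}}{constant \code{base}: no genotype effect
#'     (heritability 0).}
#'   \item{\code{xor}}{checkerboard epistasis: \code{base + gain} where the
#'     genotype codes have odd sum, \code{base} elsewhere. Interaction-
#'     driven with weak marginal effects (none at MAF 0.5).}
#'   \item{\code{threshold}}{\code{base + gain} where both SNPs carry at
#'     least one minor allele.}
#' }
#' Effects are kept strictly positive (\code{base > 0}) so the same table
#' drives both the normal and the gamma generator, whose shape parameter
#' \code{f^2} requires f > 0. Instead of a \code{gain}, a target
#' \code{heritability} may be given; the gain is then solved from the cell
#' probabilities implied by the MAFs (unit residual variance), via
#' \code{\link{calibrate_gain}}.
#'
#' @param type table shape: "null", "xor" or "threshold".
#' @param gain effect-size increment added on the active cells.
#' @param maf minor allele frequency for each causal SNP (scalar recycled to
#'   length 2); presets 0.2 and 0.4 are typical.
#' @param base baseline effect level (> 0).
#' @param heritability optional target heritability in [0, 1); overrides
#'   \code{gain}.
#' @return object of class \code{penetrance_model}: list with \code{table}
#'   (3x3), \code{maf} (length 2), \code{heritability_label}.
#' @export
penetrance_model <- function(type = c("xor", "threshold", "null"),
                             gain = 1, maf = c(0.2, 0.2), base = 1,
                             heritability = NULL) {
  type <- match.arg(type)
  maf <- rep(maf, length.out = 2L)
  if (any(maf <= 0 | maf > 0.5)) stop_("MAF must be in (0, 0.5]")
  if (base <= 0) stop_("base effect must be positive")
  if (!is.null(heritability)) {
    if (type == "null") stop_("the null table has no effect to calibrate")
    gain <- calibrate_gain(type, heritability, maf)
  }
  idx <- expand.grid(i = 0:2, j = 0:2)
  active <- switch(type,
    null = rep(FALSE, 9L),
    xor = (idx$i + idx$j) %% 2L == 1L,
    threshold = idx$i >= 1L & idx$j >= 1L)
  tab <- matrix(base + gain * as.numeric(active), 3L, 3L,
                dimnames = list(paste0("g1=", 0:2), paste0("g2=", 0:2)))
  if (type == "null") tab[] <- base
  model <- structure(list(table = tab, maf = maf,
                          heritability_label = NULL, type = type,
                          gain = if (type == "null") 0 else gain,
                          base = base),
                     class = "penetrance_model")
  model$heritability_label <- table_heritability(model)
  model
}

# HWE genotype-cell probabilities for a causal pair.
.cell_probs <- function(maf) {
  p1 <- stats::dbinom(0:2, 2L, maf[1L])
  p2 <- stats::dbinom(0:2, 2L, maf[2L])
  outer(p1, p2)
}

#' Heritability implied by a penetrance table
#'
#' With unit residual variance in both phenotype families, the heritability
#' of a table is Var(f) / (Var(f) + 1), where Var(f) is the variance of the
#' cell effect under the HWE cell probabilities implied by the MAFs.
#'
#' @param model a \code{penetrance_model}.
#' @return heritability in [0, 1).
#' @export
table_heritability <- function(model) {
  pr <- .cell_probs(model$maf)
  mu <- sum(pr * model$table)
  v <- sum(pr * (model$table - mu)^2)
  v / (v + 1)
}

#' Solve the gain giving a target heritability
#'
#' For the two-level tables ("xor", "threshold") the cell-effect variance is
#' gain^2 p(1-p) with p the HWE probability of the active cells, so the gain
#' achieving heritability h is sqrt(h / (1-h) / (p(1-p))).
#'
#' @param type "xor" or "threshold".
#' @param heritability target in (0, 1).
#' @param maf causal-pair MAFs (recycled to length 2).
#' @return positive gain.
#' @export
calibrate_gain <- function(type, heritability, maf = c(0.2, 0.2)) {
  if (heritability <= 0 || heritability >= 1)
    stop_("heritability must be in (0, 1)")
  maf <- rep(maf, length.out = 2L)
  idx <- expand.grid(i = 0:2, j = 0:2)
  active <- switch(type,
    xor = (idx$i + idx$j) %% 2L == 1L,
    threshold = idx$i >= 1L & idx$j >= 1L,
    stop_("no gain to calibrate for table type '%s'", type))
  p <- sum(.cell_probs(maf)[matrix(c(idx$i, idx$j), ncol = 2L) + 1L] *
             as.numeric(active))
  sqrt(heritability / (1 - heritability) / (p * (1 - p)))
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Independent SNPs (no linkage disequilibrium); each genotype is a
#' binomial(2, MAF) minor-allele count, i.e. HWE proportions.
#'
#' @param n samples.
#' @param p SNPs.
#' @param maf minor allele frequency, scalar or length-p vector, each in
#'   (0, 0.5].
#' @param seed integer seed.
#' @return n x p integer matrix with columns SNP1..SNPp.
#' @export
simulate_genotypes <- function(n, p, maf = 0.2, seed = 1L) {
  maf <- rep(maf, length.out = p)
  if (any(maf <= 0 | maf > 0.5)) stop_("MAF must be in (0, 0.5]")
  X <- with_seed(seed, {
    vapply(seq_len(p), function(j) stats::rbinom(n, 2L, maf[j]), integer(n))
  })
  dimnames(X) <- list(paste0("S", seq_len(n)), paste0("SNP", seq_len(p)))
  X
}

# Per-sample cell effect f for the causal pair.
.cell_effects <- function(X, model, causal_pair) {
  model$table[cbind(X[, causal_pair[1L]] + 1L, X[, causal_pair[2L]] + 1L)]
}

#' Bivariate normal phenotypes from a penetrance table
#'
#' Given the causal-pair genotypes of each sample, draws
#' (Y1, Y2) ~ MVN((f, f), Sigma) with Sigma = [[1, rho], [rho, 1]] and f the
#' sample's penetrance-cell effect: both traits share the cell mean, have
#' unit variance, and correlate at rho.
#'
#' @param X genotype matrix containing the causal pair columns.
#' @param model a \code{penetrance_model}.
#' @param rho trait correlation, |rho| < 1.
#' @param seed integer seed.
#' @param causal_pair columns of X acting through the table (default 1, 2).
#' @return n x 2 phenotype matrix (columns Y1, Y2).
#' @export
phenotypes_bivariate_normal <- function(X, model, rho = 0, seed = 1L,
                                        causal_pair = c(1L, 2L)) {
  if (abs(rho) >= 1) stop_("|rho| must be < 1")
  f <- .cell_effects(X, model, causal_pair)
  Sigma <- matrix(c(1, rho, rho, 1), 2L)
  E <- with_seed(seed, MASS::mvrnorm(length(f), mu = c(0, 0), Sigma = Sigma))
  Y <- E + cbind(f, f)
  dimnames(Y) <- list(rownames(X), c("Y1", "Y2"))
  Y
}

#' Gaussian-copula bivariate gamma phenotypes
#'
#' Skewed counterpart of \code{\link{phenotypes_bivariate_normal}}: latent
#' (z1, z2) ~ MVN(0, Sigma) are pushed through the standard normal CDF and
#' the quantile function of Gamma(shape = f^2, scale = 1/f), so each trait
#' has marginal mean f, variance 1 and skewness 2/f within a cell, while the
#' Gaussian copula supplies the dependence (Spearman correlation
#' (6/pi) asin(rho/2)).
#'
#' @inheritParams phenotypes_bivariate_normal
#' @return n x 2 phenotype matrix (columns Y1, Y2).
#' @export
phenotypes_bivariate_gamma <- function(X, model, rho = 0, seed = 1L,
                                       causal_pair = c(1L, 2L)) {
  if (abs(rho) >= 1) stop_("|rho| must be < 1")
  if (any(model$table <= 0))
    stop_("gamma phenotypes need strictly positive penetrance effects")
  f <- .cell_effects(X, model, causal_pair)
  Sigma <- matrix(c(1, rho, rho, 1), 2L)
  Z <- with_seed(seed, MASS::mvrnorm(length(f), mu = c(0, 0), Sigma = Sigma))
  U <- stats::pnorm(Z)
  Y <- cbind(stats::qgamma(U[, 1L], shape = f^2, scale = 1 / f),
             stats::qgamma(U[, 2L], shape = f^2, scale = 1 / f))
  dimnames(Y) <- list(rownames(X), c("Y1", "Y2"))
  Y
}

#' Simulate one complete dataset
#'
#' Genotypes for all SNPs at the model's MAF plus phenotypes from the chosen
#' family, with the causal pair in the first two columns by convention.
#'
#' @param n,p sample and SNP counts.
#' @param model a \code{penetrance_model}.
#' @param family "normal" or "gamma".
#' @param rho trait correlation.
#' @param seed integer seed (genotypes and phenotypes use sub-seeds derived
#'   from it).
#' @param causal_pair causal SNP columns (default 1, 2).
#' @return list with \code{genotypes}, \code{phenotypes},
#'   \code{causal_pair}, \code{model}, \code{family}, \code{rho},
#'   \code{seed}.
#' @export
simulate_dataset <- function(n = 400L, p = 20L, model,
                             family = c("normal", "gamma"), rho = 0,
                             seed = 1L, causal_pair = c(1L, 2L)) {
  family <- match.arg(family)
  seeds <- derive_seeds(seed, 2L)
  maf <- rep(model$maf[1L], p)
  maf[causal_pair] <- model$maf
  X <- simulate_genotypes(n, p, maf, seed = seeds[1L])
  Y <- switch(family,
    normal = phenotypes_bivariate_normal(X, model, rho, seeds[2L], causal_pair),
    gamma = phenotypes_bivariate_gamma(X, model, rho, seeds[2L], causal_pair))
  list(genotypes = X, phenotypes = Y, causal_pair = causal_pair,
       model = model, family = family, rho = rho, seed = seed)
}

# Canonical method names for the experiment drivers.
.method_registry <- list(
  cmdr        = list(method = "cmdr",  variant = "noise",  trait = NULL),
  cmdr_notrim = list(method = "cmdr",  variant = "notrim", trait = NULL),
  cmdr_kmeans = list(method = "cmdr",  variant = "kmeans", trait = NULL),
  mqmdr       = list(method = "mqmdr", variant = "noise",  trait = NULL),
  qmdr_y1     = list(method = "qmdr",  variant = "noise",  trait = 1L),
  qmdr_y2     = list(method = "qmdr",  variant = "noise",  trait = 2L))

.run_method <- function(name, X, Y, seed, order, n_folds, ...) {
  spec <- .method_registry[[name]]
  if (is.null(spec)) stop_("unknown method '%s'", name)
  multicmdr(X, Y, method = spec$method, variant = spec$variant,
            trait = spec$trait, order = order, n_folds = n_folds,
            seed = seed, ...)
}

#' Hit-ratio experiment
#'
#' Generates \code{n_datasets} replicate datasets from one penetrance model
#' and reports, per method, the fraction in which the true causal pair is
#' the final best order-2 model (the hit-ratio). All methods see the same
#' datasets and per-replicate seeds, so differences isolate the methods.
#'
#' @param model a \code{penetrance_model}.
#' @param methods subset of \code{c("cmdr", "cmdr_notrim", "cmdr_kmeans",
#'   "mqmdr", "qmdr_y1", "qmdr_y2")}.
#' @param n_datasets replicate datasets (default 100).
#' @param n,p,family,rho dataset design (defaults 400 samples, 20 SNPs).
#' @param n_folds CV folds (default 10).
#' @param seed master seed; replicate seeds are derived from it.
#' @param ... further options passed to \code{\link{multicmdr}}.
#' @return list with \code{hit_ratio} (named per method), \code{hits}
#'   (n_datasets x methods logical matrix) and the design parameters.
#' @export
hit_ratio_experiment <- function(model, methods = c("cmdr", "mqmdr"),
                                 n_datasets = 100L, n = 400L, p = 20L,
                                 family = "normal", rho = 0,
                                 n_folds = 10L, seed = 1L, ...) {
  bad <- setdiff(methods, names(.method_registry))
  if (length(bad)) stop_("unknown method '%s'", bad[1L])
  seeds <- derive_seeds(seed, n_datasets)
  hits <- matrix(FALSE, n_datasets, length(methods),
                 dimnames = list(NULL, methods))
  for (d in seq_len(n_datasets)) {
    sim <- simulate_dataset(n, p, model, family, rho, seed = seeds[d])
    truth <- sort(sim$causal_pair)
    for (mt in methods) {
      fit <- .run_method(mt, sim$genotypes, sim$phenotypes,
                         seed = seeds[d], order = 2L, n_folds = n_folds, ...)
      hits[d, mt] <- identical(sort(fit$best_snp_set), truth)
    }
  }
  list(hit_ratio = colMeans(hits), hits = hits, model = model,
       family = family, rho = rho, n = n, p = p, n_datasets = n_datasets,
       seed = seed)
}

#' Null false-positive-rate experiment
#'
#' Generates datasets in which phenotypes carry no genotype signal and
#' records which pair the search selects as final best. Under the null every
#' one of the choose(p, 2) pairs is equally likely, so the designated pair's
#' selection rate should be 1 / choose(p, 2) (0.0053 for p = 20).
#'
#' @param n_null_datasets number of null datasets.
#' @param n,p,family,rho,maf design of each dataset.
#' @param mode \code{"permute"} (default): simulate a causal dataset from
#'   \code{model} and permute its phenotype rows, destroying the
#'   association; \code{"direct"}: draw phenotypes from a constant (null)
#'   table.
#' @param model penetrance model for \code{mode = "permute"} (default an
#'   xor table at heritability 0.1).
#' @param method search method name (see
#'   \code{\link{hit_ratio_experiment}}).
#' @param designated_pair the pair whose selection rate is reported
#'   (default SNP1, SNP2).
#' @param n_folds,seed,... as in \code{\link{hit_ratio_experiment}}.
#' @return list with \code{designated_rate}, \code{pair_counts} (named
#'   vector over all pairs), \code{expected_rate} = 1/choose(p, 2), and the
#'   design parameters.
#' @export
null_fpr_experiment <- function(n_null_datasets, n = 400L, p = 20L,
                                family = "normal", rho = 0, maf = 0.2,
                                mode = c("permute", "direct"), model = NULL,
                                method = "cmdr",
                                designated_pair = c(1L, 2L),
                                n_folds = 10L, seed = 1L, ...) {
  mode <- match.arg(mode)
  if (is.null(model))
    model <- penetrance_model("xor", maf = maf, heritability = 0.1)
  seeds <- derive_seeds(seed, n_null_datasets)
  npair <- choose(p, 2L)
  pair_names <- apply(utils::combn(p, 2L), 2L, paste, collapse = ",")
  counts <- stats::setNames(integer(npair), pair_names)
  for (d in seq_len(n_null_datasets)) {
    sub <- derive_seeds(seeds[d], 2L)
    if (mode == "permute") {
      sim <- simulate_dataset(n, p, model, family, rho, seed = sub[1L])
      perm <- with_seed(sub[2L], sample.int(n))
      X <- sim$genotypes
      Y <- sim$phenotypes[perm, , drop = FALSE]
    } else {
      nullm <- penetrance_model("null", maf = maf)
      sim <- simulate_dataset(n, p, nullm, family, rho, seed = sub[1L])
      X <- sim$genotypes
      Y <- sim$phenotypes
    }
    fit <- .run_method(method, X, Y, seed = seeds[d], order = 2L,
                       n_folds = n_folds, ...)
    key <- paste(sort(fit$best_snp_set), collapse = ",")
    counts[key] <- counts[key] + 1L
  }
  dkey <- paste(sort(designated_pair), collapse = ",")
  list(designated_rate = counts[[dkey]] / n_null_datasets,
       pair_counts = counts, expected_rate = 1 / npair,
       n_null_datasets = n_null_datasets, p = p, mode = mode,
       method = method, seed = seed)
}
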