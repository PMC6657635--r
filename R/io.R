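# File readers and writers. Genotypes and phenotypes arrive as delimited
# text (tab or comma, sniffed), one header row, first column the sample ID;
# the PLINK .raw dialect (FID IID PAT MAT SEX PHENOTYPE, then one column per
# SNP of minor-allele counts) is also accepted for genotypes. Results go out
# as a ranked TSV plus a JSON run manifest.

.sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.read_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = .sniff_delim(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

.check_ids <- function(ids, path) {
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_("duplicate sample ID in %s: %s", path,
          paste(unique(dup), collapse = ", "))
  ids
}

#' Read a genotype file
#'
#' Accepts either a plain table (header row; first column sample ID;
#' remaining columns SNPs coded 0/1/2) or a PLINK \code{.raw} export
#' (recognized by its \code{FID IID PAT MAT SEX PHENOTYPE} leading columns;
#' the IID becomes the sample ID and the allele-count columns the SNPs).
#' Delimiter (tab or comma) is sniffed from the first line.
#'
#' @param path file path.
#' @return integer matrix (samples x SNPs) with sample IDs as row names and
#'   SNP IDs as column names.
#' @export
read_genotypes <- function(path) {
  df <- .read_table(path)
  plink <- ncol(df) >= 7L &&
    identical(toupper(names(df)[1:6]),
              c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  if (plink) {
    ids <- df[[2L]]
    dat <- df[, -(1:6), drop = FALSE]
  } else {
    ids <- df[[1L]]
    dat <- df[, -1L, drop = FALSE]
  }
  .check_ids(ids, path)
  X <- matrix(NA_integer_, nrow(dat), ncol(dat),
              dimnames = list(ids, names(dat)))
  for (j in seq_len(ncol(dat))) {
    v <- suppressWarnings(as.numeric(dat[[j]]))
    bad <- which(is.na(v) | !(v %in% c(0, 1, 2)))
    if (length(bad))
      stop_("invalid genotype '%s' at row %d, column %d (%s) of %s",
            dat[bad[1L], j], bad[1L], j, names(dat)[j], path)
    X[, j] <- as.integer(v)
  }
  X
}

#' Read a phenotype file
#'
#' Plain table: header row, first column sample ID, remaining columns
#' numeric traits. Missing or non-numeric cells are rejected with the sample
#' ID named (handle missing phenotypes before analysis).
#'
#' @param path file path.
#' @return numeric matrix (samples x traits) with sample IDs as row names.
#' @export
read_phenotypes <- function(path) {
  df <- .read_table(path)
  ids <- .check_ids(df[[1L]], path)
  dat <- df[, -1L, drop = FALSE]
  Y <- matrix(NA_real_, nrow(dat), ncol(dat),
              dimnames = list(ids, names(dat)))
  for (j in seq_len(ncol(dat))) {
    v <- suppressWarnings(as.numeric(dat[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_("missing or non-numeric value for sample '%s', trait '%s' in %s",
            ids[bad[1L]], names(dat)[j], path)
    Y[, j] <- v
  }
  Y
}

#' Read a 3x3 penetrance table from CSV
#'
#' @param path CSV/TSV with 3 rows and 3 numeric columns (no header), rows
#'   indexed by SNP1 genotype 0/1/2, columns by SNP2 genotype.
#' @param maf causal-pair MAF to attach (default 0.2).
#' @return a \code{penetrance_model}.
#' @export
read_penetrance <- function(path, maf = c(0.2, 0.2)) {
  tab <- as.matrix(utils::read.table(path, header = FALSE,
                                     sep = .sniff_delim(path)))
  if (!all(dim(tab) == c(3L, 3L)) || !is.numeric(tab))
    stop_("penetrance table must be a numeric 3x3 matrix")
  dimnames(tab) <- list(paste0("g1=", 0:2), paste0("g2=", 0:2))
  model <- structure(list(table = tab, maf = rep(maf, length.out = 2L),
                          heritability_label = NULL, type = "custom",
                          gain = NA_real_, base = NA_real_),
                     class = "penetrance_model")
  model$heritability_label <- table_heritability(model)
  model
}

#' Align genotype and phenotype matrices by sample ID
#'
#' Joins on the intersection of row names (order taken from the genotypes);
#' files listing samples in different orders are handled, and an empty
#' intersection is an error.
#'
#' @param X genotype matrix with sample row names.
#' @param Y phenotype matrix with sample row names.
#' @return list with aligned \code{genotypes} and \code{phenotypes}.
#' @export
align_samples <- function(X, Y) {
  common <- intersect(rownames(X), rownames(Y))
  if (!length(common))
    stop_("no sample IDs shared between genotype and phenotype files")
  list(genotypes = X[common, , drop = FALSE],
       phenotypes = Y[common, , drop = FALSE])
}

#' Write ranked results and a run manifest
#'
#' Emits \code{results.tsv} (columns snp_set, cvc, t2_train_mean,
#' t2_test_mean, p_value) and \code{manifest.json} (configuration, seed,
#' package version, best model) into \code{out_dir}. Reruns with identical
#' inputs produce byte-identical files.
#'
#' @param fit a \code{multicmdr_fit}.
#' @param out_dir output directory (created if needed).
#' @param top how many ranked models to write (default all).
#' @return invisibly, the paths written.
#' @export
write_results <- function(fit, out_dir, top = Inf) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_("cannot create output directory %s", out_dir)
  res <- cv_results(fit, top = top)
  res$p_value <- c(if (is.null(fit$p_value)) NA_real_ else fit$p_value,
                   rep(NA_real_, max(0L, nrow(res) - 1L)))
  tsv <- file.path(out_dir, "results.tsv")
  utils::write.table(format(res, digits = 10L, trim = TRUE), tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "multicmdr",
    version = as.character(utils::packageVersion("multicmdr")),
    config = fit$config,
    seed = fit$seed,
    theta = fit$theta,
    n_retained = if (!is.null(fit$trimmed)) nrow(fit$trimmed$memberships2)
                 else length(fit$folds_id),
    best = list(
      snp_set = if (is.null(fit$snp_ids)) paste0("SNP", fit$best_snp_set)
                else fit$snp_ids[fit$best_snp_set],
      cvc = fit$cvc[fit$best],
      t2_test_mean = fit$t2_test_best,
      t2_test_by_fold = fit$t2_test[, fit$best],
      t2_train_by_fold = fit$t2_train[, fit$best],
      p_value = fit$p_value))
  js <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(results = tsv, manifest = js))
}

#' Write a simulated dataset as analysis-ready text files
#'
#' Emits \code{genotypes.tsv} and \code{phenotypes.tsv} in the layout the
#' readers accept (round-trip safe).
#'
#' @param sim result of \code{\link{simulate_dataset}}.
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gp <- file.path(out_dir, "genotypes.tsv")
  pp <- file.path(out_dir, "phenotypes.tsv")
  gdf <- data.frame(sample_id = rownames(sim$genotypes), sim$genotypes,
                    check.names = FALSE)
  pdf <- data.frame(sample_id = rownames(sim$phenotypes), sim$phenotypes,
                    check.names = FALSE)
  utils::write.table(gdf, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pdf, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genotypes = gp, phenotypes = pp))
}
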