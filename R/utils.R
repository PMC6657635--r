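# Internal helpers shared across modules.

# Evaluate `code` with a temporarily seeded RNG, restoring the caller's
# .Random.seed afterwards so library code never perturbs user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-replicate seeds below 2^31, derived from one master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

as_matrix_named <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_("%s must be a numeric matrix", what)
  x
}
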