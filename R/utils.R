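# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG state.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derivation: one global seed fans out to per-stage /
# per-replicate streams. Kept inside 32-bit integer range.
deriveSeed <- function(base, ...) {
  idx <- c(...)
  mix <- as.numeric(base) + sum(as.numeric(idx) * c(7919, 104729, 1299709)[seq_along(idx)])
  as.integer(mix %% 2147483629)
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must lie in [%s, %s] (got %s)", name, lower, upper, x),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be a whole number (got %s)", name, x), call. = FALSE)
  invisible(TRUE)
}
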