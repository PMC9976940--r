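# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All simulator / initialisation
# determinism flows through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` child seeds from one parent seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  invisible(x)
}

relu <- function(x) x * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Root-mean-square of a vector.
rms <- function(x) sqrt(mean(x^2))
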