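`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so harness sampling never perturbs user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

is_power_of_two <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1)) == 0

# deterministic sub-seeds for per-repetition streams, kept well below 2^31
# so that small integer offsets added downstream cannot overflow
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147383647L, n))
}
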