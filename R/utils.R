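# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage seed derived from a master seed; kept < 2^31.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 131L + offset) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stopf("configuration error: '%s' must be a count >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stopf("configuration error: '%s' must lie in [0, 1]", name)
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
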