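# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round to `digits` significant digits (used by printed-style overlap output).
signif2 <- function(x, digits = 2) signif(x, digits = digits)

# Recycle a per-chromosome count argument to length n.
recycle_counts <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    stop_invalid("`%s` must have length 1 or %d, got %d", what, n, length(x))
  }
  x
}

# TRUE where `value` matches `pattern`, with "*" as a wildcard.
match_field <- function(value, pattern) {
  pattern == "*" | value == pattern
}
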