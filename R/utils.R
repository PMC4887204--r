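# Internal helpers shared across modules.

# Avogadro constant (1/mol), CODATA exact value.
N_AVOGADRO <- 6.02214076e23

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'", name, "' must be a finite numeric scalar")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid("'", name, "' = ", x, " is outside its valid range")
  invisible(x)
}

# Reflect coordinates into [lo, hi] (triangle-wave fold, exact for any
# number of boundary crossings).
fold_reflect <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + pmin(y, 2 * w - y)
}

# Periodic wrap into [lo, hi).
wrap_periodic <- function(x, lo, hi) {
  lo + (x - lo) %% (hi - lo)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Log-spaced grid, used for correlation lag times.
logspace <- function(from, to, n) {
  exp(seq(log(from), log(to), length.out = n))
}
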