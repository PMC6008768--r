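# Internal helpers.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library functions with a seed argument do not disturb the
# global stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Trapezoid mean of y(t) over [t[1], t[length(t)]].
trapz_mean <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(y[1L])
  sum(diff(t) * (y[-1L] + y[-n]) / 2) / (t[n] - t[1L])
}
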