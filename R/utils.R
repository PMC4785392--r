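# Internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Nearest odd integer to x (>= 3).
roundToOdd <- function(x) {
  w <- 2L * as.integer(round((x - 1) / 2)) + 1L
  max(3L, w)
}

stopInvalid <- function(msg) stop(msg, call. = FALSE)

asTraceValues <- function(x) {
  if (is(x, "Trace")) x@values else as.numeric(x)
}
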