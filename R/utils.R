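# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# The caller's RNG stream is left untouched so seeded package functions
# compose with user code that manages its own seeds.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

.lower_tri <- function(m) m[lower.tri(m)]

.is_square_numeric <- function(m) {
  is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m)
}
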