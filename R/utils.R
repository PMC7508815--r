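## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## evaluate expr under a temporary RNG state seeded with `seed`;
## if seed is NULL, use (and advance) the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## numerically stable softmax
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}
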