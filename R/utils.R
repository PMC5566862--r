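# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Fan a master seed out into `n` independent per-task seeds (all < 2^31).
fan_seeds <- function(seed, n) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (open) x > 0 & x < 1 else x >= 0 & x <= 1)
  if (!all(ok)) stop_domain(sprintf("`%s` must lie in %s", name,
                                    if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}
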