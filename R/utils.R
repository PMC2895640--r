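# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulators never leak global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Mean-1 multiplicative lognormal noise with coefficient of variation `cv`.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

stop_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
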