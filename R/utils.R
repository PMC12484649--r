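# internal helpers shared across modules

#' Evaluate an expression under a local, restored RNG state
#'
#' All stochastic components of the package are pure functions of
#' `(arguments, seed)`: they seed a local RNG, run, and restore the caller's
#' RNG state, so two calls with the same seed are bitwise identical and never
#' disturb the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
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
  expr
}

# derive k reproducible child seeds from a parent seed (kept < 2^31)
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# population standard deviation (divides by n, not n - 1); the package's
# fixed convention for error-dispersion reporting
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
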