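#' Evaluate code with an isolated, explicit RNG state
#'
#' All generators route their randomness through this helper so that a given
#' seed yields byte-identical output regardless of the caller's RNG state,
#' and the caller's `.Random.seed` is left untouched.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

#' Integer samplers for the synthetic generators
#'
#' A sampler is any of: a single number (a point mass), an integer vector
#' (uniform over its elements), or a `function(n)` returning `n` draws.
#' `draw_from()` normalizes the three forms.
#'
#' @param sampler Sampler in one of the accepted forms.
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @examples
#' draw_from(18, 3)
#' draw_from(14:24, 5)
#' @export
draw_from <- function(sampler, n) {
  if (n == 0L) return(integer(0))
  out <- if (is.function(sampler)) {
    sampler(n)
  } else if (is.numeric(sampler) && length(sampler) == 1L) {
    rep(sampler, n)
  } else if (is.numeric(sampler)) {
    sampler[sample.int(length(sampler), n, replace = TRUE)]
  } else {
    abort("A sampler must be a number, a numeric vector, or a function(n).")
  }
  out <- as.integer(round(out))
  if (length(out) != n) abort("Sampler returned the wrong number of draws.")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}
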