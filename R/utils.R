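#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the given seed, evaluates `code`, and restores the previous global
#' RNG state so that seeded helpers never perturb the caller's stream.
#' With `seed = NULL` the expression runs on the ambient RNG unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with a stream index through a Lehmer-style step so
#' that per-subject, per-iteration and per-permutation streams are
#' decoupled while staying inside the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param k Stream index (non-negative integer).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  x <- (s * 48271 + as.numeric(k) * 69621 + 12345) %% 2147483647
  as.integer(x)
}

# stop() with a consistent prefix for configuration problems
config_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}
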