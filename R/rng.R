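#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-stream seed
#'
#' Deterministically mixes a master seed with one or more integer indices
#' (a counter-based splitting scheme), so every stage and every record of a
#' simulation draws from its own reproducible stream. The result is always
#' in `[0, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param ... integer indices identifying the sub-stream.
#' @return An integer seed.
#' @export
split_seed <- function(seed, ...) {
  idx <- c(...)
  s <- abs(as.numeric(seed)) %% 2147483647
  for (k in idx) {
    # affine mixing mod the Mersenne prime 2^31 - 1; all products < 2^53
    s <- (s * 48271 + (abs(as.numeric(k)) %% 2147483647) * 69621 + 1) %% 2147483647
  }
  as.integer(s)
}
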