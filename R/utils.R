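# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so package functions are pure
#' functions of their `seed` arguments and never disturb the caller's RNG
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and integer indices
#'
#' Deterministic mixing (linear congruential, modulo 2^31 - 1) so that
#' per-recording and per-process seeds are stable functions of the global
#' seed. All intermediates stay below 2^53, so the arithmetic is exact in
#' doubles.
#'
#' @param seed Parent integer seed.
#' @param ... Further integer indices to mix in.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 104729
  for (v in ids) {
    h <- (h * 69069 + (v %% 2147483647) * 41213 + 1) %% 2147483647
  }
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Signal an undefined-feature condition (too few peaks/intervals in a window)
# as a classed warning and return NA, so callers can exclude the segment from
# feature-based classification while keeping it for the CNN.
undefined_feature <- function(what) {
  warning(warningCondition(
    sprintf("undefined feature: %s", what),
    class = "ringaf_undefined_feature"
  ))
  NA_real_
}

`%||%` <- function(a, b) if (is.null(a)) b else a
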