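# Internal helpers: seed management and small numerics.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators stay pure functions of
#' `(arguments, seed)` and never disturb the caller's random stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named sub-stream seed from a master seed
#'
#' Deterministic mixing of a master seed with a stage/subject tag so that every
#' pipeline stage draws from its own named stream. Result fits in a 32-bit
#' signed integer.
#'
#' @param seed master seed (integer).
#' @param ... character or integer tags naming the sub-stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Dice coefficient between two logical masks
#' @param a,b logical vectors/arrays of equal length.
#' @return numeric in \[0, 1\]; 1 when both are empty.
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
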