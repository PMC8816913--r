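#' Derive a reproducible substream seed from a master seed and a key
#'
#' Generators in this package split one master seed into independent
#' substreams keyed by stable strings (e.g. `"client-2/bag-17"`), so that the
#' data produced for a given unit does not depend on the order in which other
#' units are generated. The key is hashed with a small FNV-1a style string
#' hash and folded into the master seed; the result is always a valid 32-bit
#' R integer seed.
#'
#' @param seed Integer master seed.
#' @param key Character scalar identifying the substream.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key), length(key) == 1L)
  hash <- 2166136261
  for (b in utf8ToInt(key)) {
    hash <- (bitwXor(as.integer(hash %% 2^31), b) * 16777619) %% 2147483629
  }
  as.integer((abs(seed) * 2654435761 + hash) %% 2147483629)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generation inside package
#' functions does not disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
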