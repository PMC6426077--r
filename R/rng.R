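#' Derive a reproducible substream seed
#'
#' Counter-based seed derivation: a (seed, index) pair is mixed through
#' repeated Lehmer steps (multiplier 48271, modulus 2^31 - 1, the MINSTD
#' constants) so that per-cell substreams are reproducible and independent of
#' evaluation order. All intermediate products stay below 2^53, so the
#' arithmetic is exact in double precision.
#'
#' @param seed Integer master seed.
#' @param index Non-negative integer counter (e.g. cell index).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index), length(index) == 1)
  m <- 2147483647
  a <- 48271
  x <- ((as.double(seed) %% m) + m) %% m
  x <- (x * a) %% m
  x <- (x + (as.double(index) %% m)) %% m
  x <- (x * a) %% m
  x <- (x * a) %% m
  as.integer(x)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
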