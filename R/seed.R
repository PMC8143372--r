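#' Derive a reproducible child seed from a master seed
#'
#' All stochastic operations in the package draw their randomness from one
#' master seed. Independent streams (e.g. one per simulated control sample)
#' are derived by hashing the master seed together with a string key, so that
#' adding or reordering downstream draws never perturbs other streams.
#'
#' The hash is a multiplicative congruential mix over the UTF-8 bytes of the
#' key, reduced modulo 2^31 - 1 so the result is always a valid R integer
#' seed.
#'
#' @param seed Integer master seed.
#' @param key Character scalar identifying the stream.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "control/3")
derive_seed <- function(seed, key) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number", "invalid_seed_error")
  }
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- (abs(as.double(seed)) %% m)
  for (byte in utf8ToInt(as.character(key))) {
    # 69069: classic Marsaglia multiplier; products stay below 2^53
    h <- (h * 69069 + byte) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_stream <- function(seed, key, expr) {
  withr::with_seed(derive_seed(seed, key), expr)
}
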