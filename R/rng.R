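#' Derive a reproducible sub-stream seed
#'
#' All randomness in the simulators flows from one master seed. Per-unit
#' sub-seeds (one per gene x pool, per table, per tree) are derived by
#' mixing the master seed with integer/character keys, so adding or
#' reordering units does not perturb the draws of the others.
#'
#' @param seed master seed (single integer).
#' @param ... integer or character keys identifying the sub-stream.
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- abs(seed) %% m
  for (key in list(...)) {
    if (is.character(key)) {
      key <- sum(utf8ToInt(paste(key, collapse = "|")) *
                   seq_along(utf8ToInt(paste(key, collapse = "|"))))
    }
    stopifnot(is.numeric(key), length(key) == 1, is.finite(key))
    # doubles hold the intermediate exactly: h < 2^31, multiplier < 2^17
    h <- (h * 69069 + (abs(key) %% m) * 30269 + 101) %% m
  }
  as.integer(h)
}
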