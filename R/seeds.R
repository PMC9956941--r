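#' Derive a child seed from a parent seed
#'
#' One global seed fans out to per-stage / per-unit seeds by fixed offsets, so
#' stages are reproducible independently of each other. The derivation is a
#' multiplicative hash kept inside the 32-bit signed integer range.
#'
#' @param seed parent integer seed.
#' @param ... one or more non-negative integer offsets identifying the stage,
#'   run, metabolite, fold, ... (combined in order).
#' @return a positive integer seed, deterministic in `seed` and `...`.
#' @export
child_seed <- function(seed, ...) {
  offs <- c(...)
  stopifnot(length(offs) >= 1, all(offs >= 0))
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (o in offs) {
    # 48271 and 69621 are classic Lehmer multipliers; arithmetic stays exact
    # in doubles because intermediates are < 2^52
    h <- (h * 48271 + (as.numeric(o) + 1) * 69621) %% m
  }
  as.integer(h + 1)
}
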