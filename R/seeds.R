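# All randomness in the pipeline flows from one top-level integer seed.
# Stages draw from named substreams so each stage is independently
# reproducible regardless of how much randomness other stages consumed.

#' Derive a deterministic substream seed
#'
#' Maps a `(seed, name)` pair to an integer seed below 2^31. Used by the
#' pipeline stages (`"mask"`, `"placement"`, `"noise"`, ...) so stages never
#' share or perturb each other's random streams.
#'
#' @param seed top-level integer seed.
#' @param name substream label.
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(name))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((abs(seed) * 2654435 + h) %% 2147483647)
}

# Run `expr` under `seed` when given, otherwise with the ambient RNG.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
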