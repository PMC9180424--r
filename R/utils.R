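`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a derived, reproducible RNG substream without disturbing
# the caller's RNG state. Offsets keep stages of a pipeline independent
# while everything flows from a single user seed.
with_substream <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  derived <- (as.integer(seed) + as.integer(offset) * 10007L) %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derived)
  force(code)
}
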