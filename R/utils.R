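# Run code under a fixed seed, restoring the caller's RNG state, so all
# package randomness flows through explicit seed arguments.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a stream-specific sub-seed below 2^31 from a master seed.
.sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647)
}
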