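# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps all package-level randomness
# insulated from (and reproducible independently of) the session RNG.
withr_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed, so that
# distinct stages of a run never share an RNG stream.
derive_seed <- function(seed, stream) {
  # doubles stay exact here: seed < 2^31 and 2^31 * 7919 < 2^53
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}

# Round-half-up clipping of a continuous latent rating onto an integer scale.
clip_rating <- function(x, lo, hi) {
  pmin(hi, pmax(lo, round(x)))
}
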