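# Shared internals.

# Seed the RNG locally; caller restores the previous state via $restore().
# Keeps package functions deterministic per-seed without clobbering the
# caller's random stream.
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
}

# run fn under a local seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, fn) {
  rng <- local_rng(seed)
  on.exit(rng$restore(), add = TRUE)
  fn()
}

setNames <- stats::setNames
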