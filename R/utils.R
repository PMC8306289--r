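# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific seed from a top-level seed and a stage name, so
# pipeline stages can be re-run in isolation yet remain jointly
# reproducible. Polynomial rolling hash of the stage name folded with the
# seed, kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  mod <- 2147483647
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% mod
  as.integer((as.numeric(seed) %% mod * 48271 + h) %% mod)
}

# Short stable hexadecimal digest of any R object (polynomial hash over
# its serialization), used to stamp configs into output manifests.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  mod <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% mod
  sprintf("%08x", as.integer(h))
}
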