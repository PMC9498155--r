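# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package randomness goes through
# this so no function perturbs global RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of per-item seeds from one master seed, each < 2^31.
deriveSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnotScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be a single number", name))
  invisible(x)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

asIntegerStrict <- function(x, name) {
  if (any(is.na(x)) || any(x != as.integer(x)))
    stop(sprintf("%s must be integer-valued", name))
  as.integer(x)
}
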