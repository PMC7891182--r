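# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-away-from-zero; used for the sparsity edge count K so the
# retained-edge count is deterministic across platforms (base round() is
# banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so seeded internals never perturb the user's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible per-unit substream seed from one master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(k)) %% 2147483629)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
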