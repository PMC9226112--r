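# Internal helpers shared across modules.

# Named RNG substreams derived from one master seed.  Each modality draws from
# its own stream so adding or reordering one modality never perturbs the draws
# of another.  Derived seeds stay below 2^31 - 1.
substream_seed <- function(seed, stream) {
  streams <- c(
    expression = 11L, methylation = 23L, cna = 37L, mutation = 41L,
    network = 53L, survival = 67L, clinical = 71L, drg = 83L
  )
  if (!stream %in% names(streams)) {
    stop("unknown RNG stream: ", stream, call. = FALSE)
  }
  (as.integer(seed) %% 1000003L) * 1009L + streams[[stream]]
}

# Evaluate `fn()` under a given seed, restoring the caller's RNG state.
eval_with_seed <- function(seed, fn) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# Reverse cumulative sums down each column: out[i, j] = sum_{k >= i} m[k, j].
rev_cumsum_matrix <- function(m) {
  m <- as.matrix(m)
  apply(m, 2L, function(col) rev(cumsum(rev(col))))
}

is_count <- function(x, allow_zero = FALSE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) &&
    (x > 0 || (allow_zero && x >= 0))
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

is_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}

# Tiny FNV-1a hash over the serialized configuration, used for run manifests.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
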