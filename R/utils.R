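# Internal helpers shared across modules.

# Derive a deterministic 32-bit sub-seed from a master seed and a stream name,
# so that independent random processes (noise, init, mutation, editing) do not
# share a stream. Plain polynomial hash; stays below 2^31.
subSeed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` with a temporary RNG state seeded from (seed, name),
# restoring the caller's RNG state afterwards.
withSubSeed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(subSeed(seed, name))
  expr
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Pearson correlation between two equal-length numeric vectors.
corOf <- function(a, b) stats::cor(as.numeric(a), as.numeric(b))
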