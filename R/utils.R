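# Small internal helpers.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded components do not interfere with each other.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed: one global seed fans out to labeled
# components (folds, effects, censoring, ...) so each is independently
# reproducible. Kept well below 2^31.
seed_stream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483399)
}

# Row subset of a cancer_dataset, preserving canonical order.
subset_rows <- function(dataset, idx) {
  dataset$X <- dataset$X[idx, , drop = FALSE]
  dataset$y <- dataset$y[idx]
  dataset$delta <- dataset$delta[idx]
  dataset$n <- length(idx)
  dataset
}
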