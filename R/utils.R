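# Internal helpers shared across modules.

# Deterministic 31-bit string hash (polynomial rolling hash mod a prime).
# All arithmetic stays below 2^53 so plain doubles are exact.
str_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483563
  h
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed below 2^31 from a master seed and a string tag.
derive_seed <- function(seed, tag) {
  (as.numeric(seed) %% 2147483563 * 10007 + str_hash(tag)) %% 2147483563
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Blinded placeholder tokens used throughout the pipeline.
BLINDED_TOKENS <- c("PROT1", "PROT2", "PROT")

is_blinded_token <- function(tok) tok %in% BLINDED_TOKENS
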