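`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All stochastic package code goes through
# this so that record-level seeds fully determine output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(expr)
}

# Stable string hash -> positive integer seed below 2^31 - 1. Used to derive
# one RNG stream per synthetic record from the master seed and the record
# key, so any subset of a cohort regenerates identically regardless of
# generation order. Polynomial rolling hash; all intermediates stay well
# within double precision.
hash_seed <- function(master_seed, key) {
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}
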