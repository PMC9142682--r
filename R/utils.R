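# internal helpers shared across modules

# Evaluate `expr` under a locally seeded RNG, restoring the caller's
# .Random.seed afterwards so simulation functions are reproducible without
# clobbering the session stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; double arithmetic avoids integer
# overflow and the modulus keeps results below 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 1103 + as.numeric(k) * 12289) %% 2147483629
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min))
  }
}
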