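# Internal randomness helpers. Every seeded operation evaluates under its own
# seed and restores the caller's RNG state, so package calls never perturb a
# user's random stream.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Counter-based seed derivation: mixing (master_seed, index, level ordinal)
# through a multiplicative-congruential step mod a prime below 2^31. Adding a
# level to a battery never changes another level's per-matrix seeds.
derive_seed <- function(master_seed, index, level_ordinal) {
  p <- 2147483629
  s <- as.numeric(master_seed) %% p
  s <- (s * 69069 + as.numeric(index)) %% p
  s <- (s * 69069 + as.numeric(level_ordinal)) %% p
  as.integer(s) + 1L
}

check_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
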