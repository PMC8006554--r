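# internal helpers shared across modules

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package go
# through this so no function touches global RNG state.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x)
}

# significance tiers used throughout the correlation / group-comparison output
signif_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.01) "**" else if (p < 0.05) "*" else if (p < 0.1) "+" else ""
}
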