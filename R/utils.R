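# Seed plumbing: all randomness flows from explicit seeds; the global RNG
# state is saved and restored around every seeded computation.

with_local_seed <- function(seed, code) {
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

# Deterministic child seed from a master seed, kept inside 32-bit range.
derive_seed <- function(master, index, salt = 0L) {
  m <- (as.numeric(master) %% 1000003) + 1
  ((m * 48271 + as.numeric(index) * 16807 + as.numeric(salt) * 69621) %%
      2147483647)
}

round_half_up <- function(x) floor(x + 0.5)
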