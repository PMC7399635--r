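# Deterministic fan-out of one master seed into independent stream seeds.
# Keeps every derived seed a valid 32-bit R integer.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 1103515245 + as.numeric(p) + 12345) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
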