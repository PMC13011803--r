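# internal helpers

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
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
    })
    set.seed(seed)
  }
  expr
}

# Per-stage seeds derived from one root seed; offsets are small so the
# result stays a valid 32-bit integer for typical root seeds.
derive_seed <- function(root, offset) {
  if (is.null(root)) return(NULL)
  as.integer((as.numeric(root) + offset) %% .Machine$integer.max)
}

# Mean-preserving multiplicative lognormal noise with a given CV:
# sigma^2 = log(1 + CV^2), mu = -sigma^2 / 2.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
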