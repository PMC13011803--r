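# shared fixtures, built in code

# a tiny hand-made intensity matrix: 1 source, 3 replicates, 4 days
tiny_intensity <- function(values, normalized = FALSE, source = "srcA") {
  days <- c(1, 4, 7, 14)
  samples <- expand.grid(replicate = 1:3, day = days)
  samples <- data.frame(
    sample_id = sprintf("%s_r%d_d%d", source, samples$replicate, samples$day),
    source = source, replicate = samples$replicate, day = samples$day,
    is_control = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(values) == nrow(samples))
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  }
  colnames(values) <- samples$sample_id
  intensity_matrix(values, samples, normalized = normalized)
}

# a small but complete simulation: 2 sources, quick to run
small_sim_config <- function(seed = 1, ...) {
  simulation_config(n_sources = 2, n_formulae = 200, seed = seed, ...)
}

# fully deterministic dynamics (no measurement, process or dropout noise)
noiseless <- function(cfg) {
  cfg$noise_cv <- 0
  cfg$abundance_noise_cv <- 0
  cfg$process_noise_sd <- 0
  cfg$dropout_prob <- 0
  cfg$include_controls <- FALSE
  cfg
}

# random compositional matrix (samples in columns, columns sum to 1)
random_composition <- function(n_feat, n_samp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rlnorm(n_feat * n_samp), n_feat, n_samp,
              dimnames = list(sprintf("f%03d", seq_len(n_feat)),
                              sprintf("s%03d", seq_len(n_samp))))
  sweep(x, 2, colSums(x), "/")
}

# brute-force Spearman: explicit midranks + textbook Pearson formula
spearman_bruteforce <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# brute-force exact multinomial p for k = 3 categories
multinomial_bruteforce <- function(observed, probs) {
  n <- sum(observed)
  grid <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
  grid <- grid[rowSums(grid) == n, ]
  pr <- apply(grid, 1, function(v) {
    factorial(n) / prod(factorial(v)) * prod(probs^v)
  })
  p_obs <- factorial(n) / prod(factorial(observed)) * prod(probs^observed)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# direct one-factor PERMANOVA pseudo-F from group distance sums
permanova_groupsum_F <- function(D, groups) {
  D <- as.matrix(D)
  n <- nrow(D)
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    Dg <- D[idx, idx]
    ss_within <- ss_within + sum(Dg[upper.tri(Dg)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}
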