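test_that("Bray-Curtis reproduces hand arithmetic and its bounds", {
  x <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3))
  rownames(x) <- paste0("f", 1:3)
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["a", "b"], 4 / 12, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  disj <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  set.seed(9)
  m <- random_composition(40, 15)
  dm <- as.matrix(bray_curtis(m))
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  zz <- cbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("Bray-Curtis matches the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(10)
  m <- random_composition(60, 20)
  ours <- as.matrix(bray_curtis(m))
  ref <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("PCoA embeds a 3-point line exactly and handles degenerate input", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ord <- pcoa(d)
  pos <- sum(ord$eigenvalues > 1e-8 * max(ord$eigenvalues))
  expect_equal(pos, 1)
  rec <- as.matrix(dist(ord$coords[, 1]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  zero <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ord0 <- pcoa(zero)
  expect_true(all(ord0$coords == 0))
  expect_error(pcoa(matrix(0, 2, 2)), "too few")
})

test_that("PCoA reconstructs Euclidean configurations and counts negatives", {
  set.seed(12)
  pts <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(paste0("s", 1:20), NULL))
  ord <- pcoa(dist(pts))
  expect_equal(unname(as.matrix(dist(ord$coords))),
               unname(as.matrix(dist(pts))), tolerance = 1e-9)
  expect_equal(ord$n_negative_eigenvalues, 0)
  expect_equal(sum(ord$prop_explained), 1, tolerance = 1e-9)
  # Bray-Curtis on sparse profiles is non-Euclidean: negative eigenvalues
  # are counted and warned about
  set.seed(2)
  m <- matrix(rlnorm(20 * 15) * rbinom(20 * 15, 1, 0.4), 20, 15,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:15)))
  m <- sweep(m, 2, colSums(m), "/")
  expect_warning(ordb <- pcoa(bray_curtis(m)), "negative eigenvalue")
  expect_gt(ordb$n_negative_eigenvalues, 0)
  expect_lte(sum(ordb$prop_explained), 1 + 1e-12)
  skip_if_not_installed("vegan")
  ref <- cmdscale(dist(pts), k = 3)
  expect_equal(abs(cor(ord$coords[, 1], ref[, 1])), 1, tolerance = 1e-9)
})

test_that("vector fitting recovers known directions and flags constants", {
  set.seed(13)
  coords <- matrix(rnorm(60), 30, 2,
                   dimnames = list(paste0("s", 1:30), c("Axis1", "Axis2")))
  ord <- structure(list(coords = coords), class = "pcoa_ordination")
  vars <- data.frame(v1 = coords[, 1],
                     v2 = coords[, 1] + coords[, 2],
                     flat = rep(1, 30))
  fit <- envfit_vectors(ord, vars, n_perm = 99, seed = 1)
  expect_equal(abs(fit$axis1[1]), 1, tolerance = 1e-9)
  expect_equal(fit$r2[1], 1, tolerance = 1e-9)
  expect_lt(fit$p_value[1], 0.05)
  # equal mix: direction cosines sqrt(1/2) each (up to sign)
  expect_equal(abs(fit$axis1[2]), sqrt(0.5), tolerance = 1e-9)
  expect_equal(abs(fit$axis2[2]), sqrt(0.5), tolerance = 1e-9)
  expect_true(fit$zero_variance[3])
  expect_equal(fit$r2[3], 0)
  expect_equal(fit$p_value[3], 1)
})

test_that("vector-fit p-values are calibrated for pure noise", {
  set.seed(14)
  coords <- matrix(rnorm(60), 30, 2,
                   dimnames = list(paste0("s", 1:30), NULL))
  ord <- structure(list(coords = coords), class = "pcoa_ordination")
  p <- replicate(40, {
    envfit_vectors(ord, data.frame(v = rnorm(30)), n_perm = 199,
                   seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(p > 0.05), 0.8)
})

test_that("Procrustes m2 is invariant, symmetric, and complements protest r", {
  set.seed(15)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- 3.2 * X %*% R
  Y[, 1] <- -Y[, 1]  # reflection
  Y <- Y + 5         # translation
  rownames(Y) <- rownames(X)
  pr <- procrustes_protest(X, Y, n_perm = 99, seed = 1)
  expect_equal(pr$m2, 0, tolerance = 1e-12)
  Z <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  ab <- procrustes_protest(X, Z, n_perm = 99, seed = 1)
  ba <- procrustes_protest(Z, X, n_perm = 99, seed = 1)
  expect_equal(ab$m2, ba$m2, tolerance = 1e-9)
  expect_equal(ab$protest_r^2 + ab$m2, 1, tolerance = 1e-12)
  bad <- Z; rownames(bad) <- paste0("t", 1:20)
  expect_error(procrustes_protest(X, bad), "differ")
})

test_that("Procrustes m2 matches vegan's symmetric procrustes", {
  skip_if_not_installed("vegan")
  set.seed(16)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), NULL))
  Y <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), NULL))
  ours <- procrustes_protest(X, Y, n_perm = 9, seed = 1)
  ref <- vegan::procrustes(X, Y, symmetric = TRUE)
  expect_equal(ours$m2, ref$ss, tolerance = 1e-9)
})

test_that("protest keeps its size under independent configurations", {
  set.seed(17)
  p <- replicate(20, {
    X <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
    Y <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
    procrustes_protest(X, Y, n_perm = 199, seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(p > 0.05), 0.8)
})
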