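make_pair <- function(ab_values, int_values, source = "srcA") {
  days <- c(1, 4, 7, 14)
  samples <- expand.grid(replicate = 1:3, day = days)
  samples <- data.frame(
    sample_id = sprintf("%s_r%d_d%d", source, samples$replicate, samples$day),
    source = source, replicate = samples$replicate, day = samples$day,
    is_control = FALSE, stringsAsFactors = FALSE)
  colnames(ab_values) <- samples$sample_id
  colnames(int_values) <- samples$sample_id
  list(ab = abundance_matrix(ab_values, samples, normalized = TRUE),
       int = intensity_matrix(int_values, samples, normalized = TRUE))
}

test_that("species-formula correlations recover exact relationships", {
  # species 1 tracks formula A exactly (affine), is anti to formula B
  a <- seq(0.2, 0.4, length.out = 12)
  ab <- rbind(sp1 = a, sp2 = 1 - a)
  fa <- 0.1 + 2 * a
  fb <- max(fa) + 0.05 - fa
  int <- rbind(A = fa, B = fb)
  int <- sweep(int, 2, colSums(int), "/")
  ab <- sweep(ab, 2, colSums(ab), "/")
  pr <- make_pair(ab, int)
  sc <- correlate_species(pr$ab, pr$int)
  get <- function(sp, f) sc$rho[sc$species == sp & sc$formula_id == f]
  expect_equal(get("sp1", "A"), 1)
  expect_equal(get("sp1", "B"), -1)
  expect_equal(get("sp2", "A"), -1)
  expect_equal(sc$n_points[1], 12)
})

test_that("constant species series are excluded as undefined", {
  ab <- rbind(sp1 = rep(0.5, 12), sp2 = rep(0.5, 12))
  int <- matrix(runif(24), 2, 12, dimnames = list(c("A", "B"), NULL))
  int <- sweep(int, 2, colSums(int), "/")
  pr <- make_pair(ab, int)
  sc <- correlate_species(pr$ab, pr$int)
  expect_equal(nrow(sc), 0)
})

test_that("planted consumers anticorrelate perfectly at zero noise", {
  cfg <- noiseless(simulation_config(n_sources = 1, n_formulae = 150,
                                     n_consumed_per_class = 3, seed = 51))
  sim <- simulate_microcosm(cfg)
  sc <- correlate_species(sim$abundance, sim$intensity)
  tr <- sim$truth[sim$truth$kind == "consume", ]
  hit <- match(paste(tr$species, tr$formula_id, tr$source),
               paste(sc$species, sc$formula_id, sc$source))
  expect_true(all(sc$rho[hit] == -1))
})

test_that("resource-use profiles turn selections into class proportions", {
  ann <- data.frame(formula_id = sprintf("f%02d", 1:10),
                    compound_class = "lignin-like")
  corrs <- data.frame(species = "sp1", formula_id = ann$formula_id,
                      source = "a", rho = c(rep(-0.9, 2), runif(8, -0.2, 0.2)))
  corrs$selected_pos <- FALSE
  corrs$selected_neg <- corrs$rho < -0.5
  attr(corrs, "realized_cutoff") <- -0.5
  pu <- putative_use(corrs, ann)
  expect_equal(pu$profile$n_class, 10)
  expect_equal(pu$profile$k_used, 2)
  expect_equal(pu$profile$proportion_used, 0.2)
  expect_equal(unname(pu$species_means["sp1"]), 0.2)
})

test_that("under the null every species selects about the top fraction", {
  set.seed(52)
  sim <- suppressWarnings(simulate_microcosm(
    simulation_config(n_sources = 3, n_formulae = 300,
                      n_consumed_per_class = 0, n_produced = 0, seed = 52)))
  sc <- correlate_species(sim$abundance, sim$intensity)
  pu <- suppressWarnings(putative_use(sc, sim$annotations,
                                      top_fraction = 0.025))
  sel_rate <- tapply(sc$rho <= pu$realized_cutoff, sc$species, mean)
  expect_true(all(abs(sel_rate - 0.025) < 0.02))
})

test_that("the stratified permutation test preserves strata and finds dense species", {
  set.seed(53)
  cells <- expand.grid(species = paste0("sp", 1:6),
                       source = paste0("src", 1:4),
                       compound_class = paste0("cl", 1:5),
                       stringsAsFactors = FALSE)
  n_of_cell <- sample(20:60, 20, replace = TRUE)
  cells$n_class <- n_of_cell[as.integer(interaction(cells$source,
                                                    cells$compound_class,
                                                    drop = TRUE))]
  cells$k_used <- rbinom(nrow(cells), cells$n_class, 0.025)
  dense <- cells$species == "sp3"
  cells$k_used[dense] <- rbinom(sum(dense), cells$n_class[dense], 0.25)
  cells$proportion_used <- cells$k_used / cells$n_class
  fit <- species_difference_test(cells, n_perm = 999, seed = 1)
  expect_lte(fit$p_value, 0.01)
  expect_equal(names(which.max(fit$species_means)), "sp3")
  sp3_pairs <- fit$pairwise$species_a == "sp3" | fit$pairwise$species_b == "sp3"
  expect_true(all(fit$pairwise$p_value[sp3_pairs] < 0.05))
  # reproducible under the same seed
  fit2 <- species_difference_test(cells, n_perm = 999, seed = 1)
  expect_identical(fit$p_value, fit2$p_value)
})

test_that("the species test keeps its size under an exchangeable null", {
  set.seed(54)
  p <- replicate(100, {
    cells <- expand.grid(species = paste0("sp", 1:4),
                         source = paste0("src", 1:4),
                         compound_class = paste0("cl", 1:4),
                         stringsAsFactors = FALSE)
    cells$n_class <- 40
    cells$k_used <- rbinom(nrow(cells), 40, 0.025)
    cells$proportion_used <- cells$k_used / cells$n_class
    species_difference_test(cells, n_perm = 199,
                            seed = sample.int(1e6, 1))$p_value
  })
  expect_lte(mean(p < 0.05), 0.1)
})

test_that("joint depletion intersects the two screens correctly", {
  species_corrs <- data.frame(
    species = rep("sp1", 30), formula_id = sprintf("f%02d", 1:30),
    source = "a", rho = c(rep(-0.95, 5), runif(25, -0.2, 0.2)))
  species_corrs$selected_pos <- FALSE
  species_corrs$selected_neg <- species_corrs$rho < -0.5
  time_corrs <- data.frame(formula_id = sprintf("f%02d", 1:30), source = "a",
                           rho = c(rep(-0.9, 3), runif(27, -0.2, 0.2)))
  time_corrs$selected_pos <- FALSE
  time_corrs$selected_neg <- time_corrs$rho < -0.5
  jd <- joint_depletion(species_corrs, time_corrs)
  expect_equal(jd$per_cell$n_linked, 5)
  expect_equal(jd$per_cell$joint_count, 3)
  expect_equal(jd$per_cell$fraction_also_declining, 0.6)
  # empty declining set
  time_none <- time_corrs
  time_none$selected_neg <- FALSE
  jd0 <- joint_depletion(species_corrs, time_none)
  expect_equal(jd0$per_cell$joint_count, 0)
  # disjoint formula universes are an error
  other <- time_corrs
  other$formula_id <- sprintf("g%02d", 1:30)
  expect_error(joint_depletion(species_corrs, other), "disjoint")
})

test_that("random joint counts match the hypergeometric expectation", {
  set.seed(55)
  N <- 200; a <- 30; b <- 25
  counts <- replicate(300, {
    sa <- sample(N, a); sb <- sample(N, b)
    length(intersect(sa, sb))
  })
  expect_equal(mean(counts), a * b / N, tolerance = 3 * sd(counts) / sqrt(300))
})

test_that("zero-noise planted consumers deplete their whole resource set", {
  cfg <- noiseless(simulation_config(n_sources = 1, n_formulae = 150,
                                     n_consumed_per_class = 3, seed = 56))
  sim <- simulate_microcosm(cfg)
  sc <- correlate_species(sim$abundance, sim$intensity)
  tc <- correlate_time(sim$intensity)
  sthr <- percentile_threshold(sc, 0.025, "negative")
  tthr <- percentile_threshold(tc, 0.025, "negative")
  jd <- joint_depletion(sthr, tthr)
  tr <- sim$truth[sim$truth$kind == "consume", ]
  jkey <- paste(jd$links$species, jd$links$formula_id, jd$links$source)
  expect_true(all(paste(tr$species, tr$formula_id, tr$source) %in% jkey))
})
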