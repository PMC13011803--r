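test_that("formula annotation reproduces hand-computed chemistry", {
  ann <- annotate_formulae(c("CH4", "C6H6", "C6H12O6"))
  # methane: AI_mod numerator zero, fully saturated, biolabile
  expect_equal(ann$ai_mod[1], 0)
  expect_equal(ann$hc[1], 4)
  expect_true(ann$bioavailable[1])
  # benzene: AI_mod = 4/6, H/C = 1, O/C = 0
  expect_equal(ann$ai_mod[2], 4 / 6, tolerance = 1e-12)
  expect_equal(ann$hc[2], 1)
  expect_equal(ann$oc[2], 0)
  # glucose: raw AI_mod negative, reported 0; monoisotopic mass
  expect_equal(ann$ai_mod[3], 0)
  expect_equal(ann$hc[3], 2)
  expect_equal(ann$oc[3], 1)
  expect_equal(ann$neutral_mass[3], 180.0634, tolerance = 1e-4)
})

test_that("formula strings parse in Hill order with implied counts", {
  p <- parse_molecular_formula(c("C10H12O5", "C6H13NO2S", "CH4"))
  expect_equal(p$c, c(10L, 6L, 1L))
  expect_equal(p$h, c(12L, 13L, 4L))
  expect_equal(p$n, c(0L, 1L, 0L))
  expect_equal(p$o, c(5L, 2L, 0L))
  expect_equal(p$s, c(0L, 1L, 0L))
  expect_error(parse_molecular_formula("C6H12Xe2"), "unsupported")
})

test_that("formulae without carbon or hydrogen are rejected", {
  expect_error(annotate_formulae(data.frame(c = 0, h = 4, n = 0, o = 0,
                                            s = 0, p = 0)), "invalid formula")
  expect_error(annotate_formulae(data.frame(c = 6, h = 0, n = 0, o = 0,
                                            s = 0, p = 0)), "invalid formula")
})

test_that("annotation is pure and AI_mod stays in [0, 1] across a sweep", {
  set.seed(11)
  df <- data.frame(c = sample(1:60, 500, TRUE), h = sample(1:120, 500, TRUE),
                   n = sample(0:4, 500, TRUE), o = sample(0:40, 500, TRUE),
                   s = sample(0:4, 500, TRUE), p = sample(0:4, 500, TRUE))
  a1 <- annotate_formulae(df)
  a2 <- annotate_formulae(df)
  expect_identical(a1, a2)
  expect_true(all(a1$ai_mod >= 0 & a1$ai_mod <= 1))
  expect_equal(a1$hc, df$h / df$c)
  expect_equal(a1$oc, df$o / df$c)
})

test_that("van Krevelen rectangles classify known points and partition the plane", {
  expect_equal(assign_compound_class(2.0, 1.0), "carbohydrate-like")
  expect_equal(assign_compound_class(1.0, 0.3), "lignin-like")
  expect_equal(assign_compound_class(0.5, 0.2), "condensed aromatic-like")
  expect_equal(assign_compound_class(1.8, 0.1), "lipid-like")
  expect_equal(assign_compound_class(0.6, 0.8), "tannin-like")
  expect_equal(assign_compound_class(2.6, 0.5), "unassigned")
  # grid: every point gets exactly one deterministic label
  g <- expand.grid(hc = seq(0.01, 3, by = 0.01), oc = seq(0, 1.5, by = 0.01))
  cls <- assign_compound_class(g$hc, g$oc)
  expect_false(anyNA(cls))
  expect_identical(cls, assign_compound_class(g$hc, g$oc))
  expect_setequal(unique(cls), c(vk_class_table()$class, "unassigned"))
})

test_that("TIC normalization scales columns to 1 and is idempotent", {
  m <- tiny_intensity(matrix(c(2, 3, 5), 3, 12))
  n1 <- normalize_tic(m)
  expect_equal(unname(n1$values[, 1]), c(0.2, 0.3, 0.5))
  expect_true(n1$normalized)
  n2 <- normalize_tic(n1)
  expect_equal(n1$values, n2$values, tolerance = 1e-15)
  m2 <- tiny_intensity(matrix(c(0, 0, 7), 3, 12))
  expect_equal(unname(normalize_tic(m2)$values[, 3]), c(0, 0, 1))
  vals <- matrix(1, 3, 12); vals[, 5] <- 0
  expect_error(normalize_tic(tiny_intensity(vals)), "zero total intensity")
})

test_that("replicate presence filter applies the 2-of-3 rule per (source, day)", {
  # 3 formulae x 12 samples (3 reps x 4 days); formula 3 is the filler that
  # keeps every column's total positive
  vals <- matrix(0, 3, 12)
  vals[3, ] <- 1
  day1 <- 1:3  # columns of day 1 are replicates 1:3
  vals[1, day1[1:2]] <- 5   # present in 2 of 3 -> kept
  vals[2, day1[1]] <- 5     # present in 1 of 3 -> zeroed
  m <- normalize_tic(tiny_intensity(vals))
  f <- replicate_presence_filter(m, min_reps = 2)
  expect_true(all(f$values[1, day1[1:2]] > 0))
  expect_true(all(f$values[2, ] == 0))
  # min_reps = 1: only renormalization
  f1 <- replicate_presence_filter(m, min_reps = 1)
  expect_equal(f1$values, m$values, tolerance = 1e-12)
  # never creates presence
  set.seed(7)
  r <- matrix(rbinom(36, 1, 0.5) * runif(36), 3, 12)
  r[3, ] <- 1
  mr <- normalize_tic(tiny_intensity(r))
  fr <- replicate_presence_filter(mr)
  expect_true(all((fr$values > 0) <= (mr$values > 0)))
})

test_that("filter warns and passes groups with too few replicates", {
  samples <- data.frame(sample_id = c("a_r1_d1", "a_r1_d4"), source = "a",
                        replicate = 1, day = c(1, 4), is_control = FALSE)
  vals <- matrix(c(1, 3, 2, 2), 2, 2,
                 dimnames = list(c("f1", "f2"), samples$sample_id))
  m <- normalize_tic(intensity_matrix(vals, samples))
  w <- capture_warnings(f <- replicate_presence_filter(m, min_reps = 2))
  expect_match(w, "fewer than 2 replicates", all = TRUE)
  expect_length(w, 2)  # one per (source, day) group
  expect_equal(f$values, m$values, tolerance = 1e-12)
})

test_that("bulk metrics are intensity-weighted means and fractions", {
  ann <- annotate_formulae(data.frame(formula_id = c("f1", "f2"),
                                      c = c(10, 10), h = c(20, 10), n = 0,
                                      o = c(1, 3), s = 0, p = 0))
  expect_equal(ann$hc, c(2, 1))
  vals <- matrix(c(0.75, 0.25), 2, 12, dimnames = list(c("f1", "f2"), NULL))
  m <- tiny_intensity(vals, normalized = TRUE)
  b <- bulk_metrics(m, ann)
  expect_equal(b$weighted_hc[1], 1.75)
  expect_equal(b$bioavailable_fraction[1], 0.75)
  # single component and all-below-cutoff cases
  m1 <- tiny_intensity(matrix(1, 1, 12, dimnames = list("f2", NULL)),
                       normalized = TRUE)
  b1 <- bulk_metrics(m1, ann)
  expect_equal(b1$weighted_hc[1], 1)
  expect_equal(b1$bioavailable_fraction[1], 0)
  # missing annotation errors with the offending id
  m2 <- tiny_intensity(matrix(1, 1, 12, dimnames = list("zz", NULL)),
                       normalized = TRUE)
  expect_error(bulk_metrics(m2, ann), "zz")
})

test_that("bulk weighted means are convex combinations", {
  set.seed(5)
  df <- data.frame(formula_id = sprintf("f%02d", 1:30),
                   c = sample(5:30, 30, TRUE), h = sample(5:60, 30, TRUE),
                   n = 0, o = sample(0:20, 30, TRUE), s = 0, p = 0)
  ann <- annotate_formulae(df)
  vals <- random_composition(30, 12)
  rownames(vals) <- df$formula_id
  m <- tiny_intensity(vals, normalized = TRUE)
  b <- bulk_metrics(m, ann)
  expect_true(all(b$weighted_hc >= min(ann$hc) & b$weighted_hc <= max(ann$hc)))
  expect_true(all(b$weighted_mass >= min(ann$neutral_mass) &
                    b$weighted_mass <= max(ann$neutral_mass)))
  expect_true(all(b$bioavailable_fraction >= 0 & b$bioavailable_fraction <= 1))
  class_cols <- grep("^class_", names(b))
  expect_true(all(abs(rowSums(b[, class_cols]) - 1) < 1e-9))
})
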