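#' Species-by-formula Spearman correlations per DOM source
#'
#' Correlates each species' relative abundance with each formula's relative
#' intensity across the time-series samples of every source (midrank
#' Spearman over the pooled replicate samples). Control samples are
#' excluded; species with a constant series on a source are excluded as
#' undefined.
#'
#' @param ab a normalized [abundance_matrix()].
#' @param m a normalized [intensity_matrix()] sharing sample keys with `ab`.
#' @param min_samples minimum samples per source (default 6).
#' @return data.frame of class `correlation_table`: `species`,
#'   `formula_id`, `source`, `rho`, `n_points`.
#' @export
correlate_species <- function(ab, m, min_samples = 6) {
  stopifnot(inherits(ab, "sample_matrix"), inherits(m, "sample_matrix"))
  if (!ab$normalized || !m$normalized) stop("both matrices must be normalized")
  ab <- drop_controls(ab)
  m <- drop_controls(m)
  shared <- intersect(sample_ids(ab), sample_ids(m))
  if (!length(shared)) stop("matrices share no samples")
  ab <- subset_samples(ab, match(shared, sample_ids(ab)))
  m <- subset_samples(m, match(shared, sample_ids(m)))
  out <- list()
  for (s in unique(m$samples$source)) {
    cols <- which(m$samples$source == s)
    if (length(cols) < min_samples) {
      warning("source ", s, " has fewer than ", min_samples,
              " samples; skipped")
      next
    }
    Rf <- .rank_center_rows(m$values[, cols, drop = FALSE])
    Rs <- .rank_center_rows(ab$values[, cols, drop = FALSE])
    ok_f <- Rf$norm > 0
    ok_s <- Rs$norm > 0
    if (!any(ok_f) || !any(ok_s)) next
    C <- (Rs$R[ok_s, , drop = FALSE] %*% t(Rf$R[ok_f, , drop = FALSE])) /
      outer(Rs$norm[ok_s], Rf$norm[ok_f])
    out[[length(out) + 1]] <- data.frame(
      species = rep(rownames(ab$values)[ok_s], times = sum(ok_f)),
      formula_id = rep(rownames(m$values)[ok_f], each = sum(ok_s)),
      source = s, rho = as.numeric(C), n_points = length(cols),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(0), formula_id = character(0),
               source = character(0), rho = numeric(0),
               n_points = integer(0))
  rownames(res) <- NULL
  class(res) <- c("correlation_table", class(res))
  res
}

#' Putative resource-use profile from the strongest negative correlations
#'
#' Applies a pooled one-sided negative percentile cutoff (default: the
#' strongest 2.5% of the species-by-formula correlations across all DOM
#' sources) and summarizes, per (species, source, compound class), the
#' proportion of that class's tested formulae falling in the selected set,
#' plus each species' mean proportion across the class-by-source cells.
#'
#' @param corrs table from [correlate_species()] (or one already passed
#'   through [percentile_threshold()] one-sided negative).
#' @param annotations annotation table covering the formulae.
#' @param top_fraction selection fraction when `corrs` is unthresholded
#'   (default 0.025).
#' @return list of class `resource_use_profile`: `profile` (species,
#'   source, compound_class, n_class, k_used, proportion_used),
#'   `species_means` (named vector), `realized_cutoff`, `links` (the
#'   selected species-formula-source triples).
#' @export
putative_use <- function(corrs, annotations, top_fraction = 0.025) {
  if (is.null(corrs$selected_neg)) {
    corrs <- percentile_threshold(corrs, top_fraction, sided = "negative")
  }
  cls <- annotations$compound_class[match(corrs$formula_id,
                                          annotations$formula_id)]
  if (anyNA(cls)) stop("annotations missing for some formula ids")
  agg <- stats::aggregate(
    cbind(n_class = rep(1, nrow(corrs)), k_used = corrs$selected_neg),
    by = list(species = corrs$species, source = corrs$source,
              compound_class = cls),
    FUN = sum)
  agg$proportion_used <- agg$k_used / agg$n_class
  agg <- agg[order(agg$species, agg$source, agg$compound_class),
             c("species", "source", "compound_class", "n_class", "k_used",
               "proportion_used")]
  rownames(agg) <- NULL
  means <- tapply(agg$proportion_used, agg$species, mean)
  if (!any(corrs$selected_neg)) {
    warning("empty selection: resource-use profile is all zeros")
  }
  structure(list(profile = agg, species_means = means,
                 realized_cutoff = attr(corrs, "realized_cutoff"),
                 links = corrs[corrs$selected_neg,
                               c("species", "formula_id", "source", "rho")]),
            class = "resource_use_profile")
}

#' @export
print.resource_use_profile <- function(x, ...) {
  cat("<resource_use_profile> mean proportion used per species:\n")
  print(round(sort(x$species_means, decreasing = TRUE), 4))
  cat("realized cutoff rho <=", format(x$realized_cutoff, digits = 4), "\n")
  invisible(x)
}

#' Stratified permutation test for species differences in resource use
#'
#' Do species differ in the probability that a formula is classed as used?
#' The statistic is the between-species variance of the cell-averaged
#' proportions; the null shuffles species labels within each
#' (compound class, source) stratum, which preserves every cell's n_class.
#' Reports a global p-value and pairwise species contrasts (absolute
#' difference of means under the same permutations).
#'
#' @param profile the `profile` data.frame of a [putative_use()] result (or
#'   the result itself).
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed.
#' @return list of class `species_difference_test`: `statistic`, `p_value`,
#'   `species_means`, `pairwise` (species_a, species_b, diff, p_value),
#'   `n_permutations`, `seed`.
#' @export
species_difference_test <- function(profile, n_perm = 9999, seed = NULL) {
  if (inherits(profile, "resource_use_profile")) profile <- profile$profile
  species <- sort(unique(profile$species))
  if (length(species) < 2) stop("need at least 2 species")
  strata <- interaction(profile$compound_class, profile$source, drop = TRUE)
  prop <- profile$proportion_used
  sp <- factor(profile$species, levels = species)
  mean_by_species <- function(p) tapply(p, sp, mean)
  obs_means <- mean_by_species(prop)
  obs_stat <- stats::var(obs_means)
  pair_idx <- utils::combn(length(species), 2)
  obs_diff <- abs(obs_means[pair_idx[1, ]] - obs_means[pair_idx[2, ]])
  with_seed(seed, {
    hits <- 0L
    hits_pair <- rep(0L, ncol(pair_idx))
    idx_by_stratum <- split(seq_along(prop), strata)
    for (b in seq_len(n_perm)) {
      perm <- prop
      for (ix in idx_by_stratum) {
        perm[ix] <- perm[ix[sample.int(length(ix))]]
      }
      mb <- mean_by_species(perm)
      if (stats::var(mb) >= obs_stat - 1e-15) hits <- hits + 1L
      db <- abs(mb[pair_idx[1, ]] - mb[pair_idx[2, ]])
      hits_pair <- hits_pair + (db >= obs_diff - 1e-15)
    }
    pairwise <- data.frame(
      species_a = species[pair_idx[1, ]], species_b = species[pair_idx[2, ]],
      diff = as.numeric(obs_diff),
      p_value = (1 + hits_pair) / (1 + n_perm))
    structure(list(statistic = obs_stat,
                   p_value = (1 + hits) / (1 + n_perm),
                   species_means = obs_means, pairwise = pairwise,
                   n_permutations = n_perm, seed = seed),
              class = "species_difference_test")
  })
}

#' Joint species-and-time depletion counts
#'
#' Intersects the putative resource-use links (strongest negative
#' species-by-formula correlations) with the time-declining formula set
#' (strongest negative formula-by-time correlations): per (species,
#' source), the number of formulae negative in both screens, and the
#' fraction of that species' links whose formula also declines over time.
#'
#' @param species_corrs thresholded table from [correlate_species()] +
#'   [percentile_threshold()] (one-sided negative), or unthresholded (then
#'   `species_fraction` is applied).
#' @param time_corrs thresholded table from [correlate_time()] +
#'   [percentile_threshold()] (one-sided negative), or unthresholded (then
#'   `time_fraction` is applied).
#' @param species_fraction,time_fraction selection fractions used when the
#'   respective table is unthresholded (defaults 0.025).
#' @return list of class `joint_depletion`: `per_cell` (species, source,
#'   n_linked, joint_count, fraction_also_declining), `overall_fraction`,
#'   `links` (the jointly selected triples), and the two realized cutoffs.
#' @export
joint_depletion <- function(species_corrs, time_corrs,
                            species_fraction = 0.025, time_fraction = 0.025) {
  if (is.null(species_corrs$selected_neg)) {
    species_corrs <- percentile_threshold(species_corrs, species_fraction,
                                          sided = "negative")
  }
  if (is.null(time_corrs$selected_neg)) {
    time_corrs <- percentile_threshold(time_corrs, time_fraction,
                                       sided = "negative")
  }
  if (!length(intersect(species_corrs$formula_id, time_corrs$formula_id))) {
    stop("species and time correlation tables cover disjoint formula sets")
  }
  declining <- paste(time_corrs$formula_id[time_corrs$selected_neg],
                     time_corrs$source[time_corrs$selected_neg])
  linked <- species_corrs[species_corrs$selected_neg, , drop = FALSE]
  linked$joint <- paste(linked$formula_id, linked$source) %in% declining
  cells <- expand.grid(species = sort(unique(species_corrs$species)),
                       source = sort(unique(species_corrs$source)),
                       stringsAsFactors = FALSE)
  key <- paste(linked$species, linked$source)
  cells$n_linked <- as.integer(table(factor(key,
    levels = paste(cells$species, cells$source))))
  cells$joint_count <- as.integer(tapply(linked$joint,
    factor(key, levels = paste(cells$species, cells$source)), sum))
  cells$joint_count[is.na(cells$joint_count)] <- 0L
  cells$fraction_also_declining <-
    ifelse(cells$n_linked > 0, cells$joint_count / cells$n_linked, 0)
  structure(list(
    per_cell = cells,
    overall_fraction = if (nrow(linked)) mean(linked$joint) else 0,
    links = linked[linked$joint, c("species", "formula_id", "source", "rho")],
    species_cutoff = attr(species_corrs, "realized_cutoff"),
    time_cutoff = attr(time_corrs, "realized_cutoff")),
    class = "joint_depletion")
}

#' @export
print.joint_depletion <- function(x, ...) {
  cat(sprintf("<joint_depletion> %d joint links; %.1f%% of species links also decline\n",
              nrow(x$links), 100 * x$overall_fraction))
  cat(sprintf("cutoffs: species rho <= %.4f, time rho <= %.4f\n",
              x$species_cutoff, x$time_cutoff))
  invisible(x)
}
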