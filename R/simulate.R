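#' Configuration for the synthetic microcosm
#'
#' Describes a multi-source bottle incubation: several DOM sources, each
#' inoculated with the same small bacterial community, sampled in triplicate
#' on a fixed set of days. A subset of formulae on each source carries a
#' planted consumption or production link to one species; everything else is
#' inert. The defaults mirror the template experiment: 7 sources in three
#' lability groups, 3 replicates, days 1/4/7/14, 6 species (one
#' narrow-niche specialist whose links are confined to biolabile formulae of
#' its home source, plus generalists, one of which has the broadest links),
#' and ~500 formulae per source spanning the van Krevelen plane.
#'
#' @param n_sources number of DOM sources (default 7).
#' @param n_replicates replicate bottles per source (default 3).
#' @param days sampling days (default `c(1, 4, 7, 14)`).
#' @param n_species community size (default 6).
#' @param n_formulae formulae per source (default 500; at least 50).
#' @param specialist_index which species is the specialist (default 1).
#' @param consumption_rate per-day fractional decay of a consumed formula at
#'   consumer abundance 1 (default 0.2).
#' @param production_rate per-day fractional gain of a produced formula
#'   (default 0.05).
#' @param growth_yield converts a species' summed consumption flux into
#'   relative growth in the replicator update (default 30).
#' @param n_consumed_per_class planted consumed formulae per target class
#'   and source (default 8).
#' @param n_produced planted produced formulae per source (default 4).
#' @param consumed_intensity_boost factor by which consumed formulae exceed
#'   the typical initial intensity (default 5): labile target compounds are
#'   abundant constituents of their source, so their depletion moves the
#'   bulk metrics.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on peak intensities (default 0.05).
#' @param abundance_noise_cv measurement noise CV on species relative
#'   abundances (default 0.1): amplicon-derived abundances from a few
#'   thousand reads carry more noise than spectral intensities.
#' @param process_noise_sd per-day-step lognormal standard deviation of
#'   bottle-level demographic fluctuations in the replicator update
#'   (default 0.12): each replicate bottle follows its own community
#'   trajectory, as replicate incubations do.
#' @param dropout_prob detection-limit dropout rate (default 0.05): in each
#'   replicate a present formula is recorded as 0 with probability
#'   `dropout_prob * min(1, (q25 / x)^2)`, where x is its relative intensity
#'   and q25 the lower quartile of the sample's nonzero intensities — rare
#'   peaks drop out, abundant peaks essentially never do.
#' @param core_fraction fraction of each source's formulae drawn from a core
#'   shared by all sources (default 0.4).
#' @param include_controls add one no-bacteria control bottle per source
#'   (default TRUE).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_sources = 7, n_replicates = 3,
                              days = c(1, 4, 7, 14), n_species = 6,
                              n_formulae = 500, specialist_index = 1,
                              consumption_rate = 0.2, production_rate = 0.05,
                              growth_yield = 30, n_consumed_per_class = 7,
                              n_produced = 4, consumed_intensity_boost = 1,
                              noise_cv = 0.05, abundance_noise_cv = 0.1,
                              process_noise_sd = 0.12, dropout_prob = 0.05,
                              core_fraction = 0.4, include_controls = TRUE,
                              seed = 1) {
  cfg <- list(n_sources = n_sources, n_replicates = n_replicates,
              days = sort(unique(days)), n_species = n_species,
              n_formulae = n_formulae, specialist_index = specialist_index,
              consumption_rate = consumption_rate,
              production_rate = production_rate, growth_yield = growth_yield,
              n_consumed_per_class = n_consumed_per_class,
              n_produced = n_produced,
              consumed_intensity_boost = consumed_intensity_boost,
              noise_cv = noise_cv, abundance_noise_cv = abundance_noise_cv,
              process_noise_sd = process_noise_sd,
              dropout_prob = dropout_prob, core_fraction = core_fraction,
              include_controls = include_controls, seed = seed)
  stopifnot(cfg$n_sources >= 1, cfg$n_replicates >= 1, length(cfg$days) >= 2,
            cfg$n_species >= 2, cfg$consumption_rate >= 0,
            cfg$production_rate >= 0, cfg$noise_cv >= 0,
            cfg$abundance_noise_cv >= 0, cfg$process_noise_sd >= 0,
            cfg$consumed_intensity_boost >= 1,
            cfg$dropout_prob >= 0, cfg$dropout_prob < 1,
            cfg$specialist_index >= 1, cfg$specialist_index <= cfg$n_species,
            cfg$core_fraction > 0, cfg$core_fraction < 1)
  class(cfg) <- "simulation_config"
  cfg
}

#' Fresh labile-source preset
#'
#' A [simulation_config()] variant emulating incubations on a fresh, highly
#' labile substrate: the planted biolabile target compounds dominate the
#' intensity budget (`consumed_intensity_boost = 20`), as in a fresh leaf
#' leachate where the biolabile pool carries most of the signal. Their
#' depletion is then visible in the bulk descriptors: the intensity-weighted
#' H/C of the fresh source falls day over day while the summed relative
#' intensity of less-bioavailable classes rises.
#'
#' @param seed integer seed.
#' @param ... further overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
labile_preset <- function(seed = 1, ...) {
  simulation_config(consumed_intensity_boost = 20, seed = seed, ...)
}

# Source labels and lability groups for up to 7 sources; extras get generic
# recalcitrant labels.
.source_table <- function(n_sources) {
  base <- data.frame(
    source = c("leaf_leachate", "boreal_lake", "subarctic_lake",
               "subarctic_river", "subtropical_river", "temperate_marsh",
               "temperate_pond"),
    group = c("fresh_labile", "worked_labile", "worked_labile",
              "worked_labile", "recalcitrant", "recalcitrant", "recalcitrant"),
    stringsAsFactors = FALSE
  )
  if (n_sources <= 7) return(base[seq_len(n_sources), ])
  extra <- data.frame(source = sprintf("extra_source_%d", seq_len(n_sources - 7)),
                      group = "recalcitrant", stringsAsFactors = FALSE)
  rbind(base, extra)
}

.species_names <- function(cfg) {
  nm <- sprintf("generalist_%d", seq_len(cfg$n_species))
  nm[cfg$specialist_index] <- "specialist"
  idx <- setdiff(seq_len(cfg$n_species), cfg$specialist_index)
  nm[idx] <- sprintf("generalist_%d", seq_along(idx))
  nm
}

# base class mixture of the formula pool, tilted per lability group
.CLASS_PROPS <- c("lipid-like" = 0.08, "protein-like" = 0.12,
                  "amino sugar-like" = 0.08, "carbohydrate-like" = 0.10,
                  "unsaturated hydrocarbon-like" = 0.06, "lignin-like" = 0.25,
                  "tannin-like" = 0.12, "condensed aromatic-like" = 0.09,
                  "unassigned" = 0.10)

.BIO_CLASSES <- c("lipid-like", "protein-like", "amino sugar-like",
                  "carbohydrate-like")

.group_class_props <- function(group) {
  p <- .CLASS_PROPS
  if (group == "fresh_labile") {
    p[.BIO_CLASSES] <- p[.BIO_CLASSES] * 2
    p[c("lignin-like", "tannin-like", "condensed aromatic-like")] <-
      p[c("lignin-like", "tannin-like", "condensed aromatic-like")] * 0.5
  } else if (group == "worked_labile") {
    p["lignin-like"] <- p["lignin-like"] * 1.8
  } else {
    p[c("tannin-like", "condensed aromatic-like")] <-
      p[c("tannin-like", "condensed aromatic-like")] * 1.7
    p[.BIO_CLASSES] <- p[.BIO_CLASSES] * 0.7
  }
  p / sum(p)
}

# Draw element counts whose realized van Krevelen position lands in the
# requested class; mismatches from integer rounding are redrawn.
.draw_class_counts <- function(classes) {
  n <- length(classes)
  tab <- vk_class_table()
  draw_ratios <- function(cl, k) {
    if (cl == "unassigned") {
      pick <- stats::runif(k) < 0.5
      hc <- ifelse(pick, stats::runif(k, 2.45, 3.2), stats::runif(k, 0.25, 0.45))
      oc <- ifelse(pick, stats::runif(k, 0, 1.15), stats::runif(k, 0.72, 1.15))
    } else {
      r <- tab[tab$class == cl, ]
      # stay a touch inside open bounds so rounding rarely crosses them
      hc <- stats::runif(k, r$hc_lo + 0.03, r$hc_hi - 0.03)
      oc <- stats::runif(k, r$oc_lo + 0.02, max(r$oc_lo + 0.02, r$oc_hi - 0.02))
    }
    list(hc = hc, oc = oc)
  }
  C <- H <- O <- integer(n)
  todo <- seq_len(n)
  for (iter in 1:50) {
    if (!length(todo)) break
    for (cl in unique(classes[todo])) {
      idx <- todo[classes[todo] == cl]
      r <- draw_ratios(cl, length(idx))
      C[idx] <- sample(10:40, length(idx), replace = TRUE)
      H[idx] <- pmax(1L, as.integer(round(r$hc * C[idx])))
      O[idx] <- as.integer(round(r$oc * C[idx]))
    }
    realized <- assign_compound_class(H[todo] / C[todo], O[todo] / C[todo])
    todo <- todo[realized != classes[todo]]
  }
  data.frame(c = C, h = H, o = O,
             n = stats::rbinom(n, 2, 0.15), s = stats::rbinom(n, 1, 0.08),
             p = stats::rbinom(n, 1, 0.04))
}

#' Generate a molecular-formula library spanning the van Krevelen plane
#'
#' Builds a pool of CHNOSP formulae with a shared core plus source-specific
#' unique sets; the class mixture of each source's unique formulae is tilted
#' by its lability group (fresh-labile sources are rich in biolabile
#' classes, worked-labile in lignin-like, recalcitrant in tannin- and
#' condensed aromatic-like formulae), so every compound class is populated
#' and sources overlap only partially.
#'
#' @param cfg a [simulation_config()].
#' @return list with `annotations` (annotation table for the whole pool),
#'   `source_formulae` (named list of formula ids per source) and `sources`
#'   (source/lability table).
#' @export
generate_formula_library <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_formulae < 50) {
    stop("n_formulae must be at least 50 to populate all compound classes")
  }
  with_seed(derive_seed(cfg$seed, 0), {
    src <- .source_table(cfg$n_sources)
    core_n <- round(cfg$core_fraction * cfg$n_formulae)
    uniq_n <- cfg$n_formulae - core_n
    class_draw <- function(props, k) {
      sample(names(props), k, replace = TRUE, prob = props)
    }
    classes <- class_draw(.CLASS_PROPS, core_n)
    owner <- rep("core", core_n)
    for (i in seq_len(nrow(src))) {
      classes <- c(classes, class_draw(.group_class_props(src$group[i]), uniq_n))
      owner <- c(owner, rep(src$source[i], uniq_n))
    }
    counts <- .draw_class_counts(classes)
    counts$formula_id <- sprintf("F%05d", seq_len(nrow(counts)))
    ann <- annotate_formulae(counts)
    source_formulae <- lapply(src$source, function(s) {
      ann$formula_id[owner %in% c("core", s)]
    })
    names(source_formulae) <- src$source
    list(annotations = ann, source_formulae = source_formulae, sources = src)
  })
}

# target consumed class per source; the specialist's home source gets a
# strictly biolabile class, generalist sources rotate through the labile
# classes so a generalist serving several sources spans several classes
.target_classes <- function(source_index) {
  if (source_index == 1) return("amino sugar-like")
  rotation <- c("lipid-like", "amino sugar-like", "carbohydrate-like",
                "lipid-like", "amino sugar-like", "carbohydrate-like")
  rotation[(source_index - 2) %% length(rotation) + 1]
}

#' Simulate the consumer-resource microcosm
#'
#' Discrete-time dynamics between sampled days: a consumed formula's raw
#' intensity is multiplied by `(1 - rate * dt * a_s)` where `a_s` is its
#' consumer's relative abundance; a produced formula gains
#' `(1 + rate * dt * a_s)`; each species then grows by `growth_yield` times
#' its summed consumption flux in a replicator update. Each source has a
#' single consuming species (the specialist on its home source, otherwise
#' one generalist), whose planted consumption is concentrated in one target
#' compound class per source. Sampled profiles receive mean-preserving
#' lognormal multiplicative noise, per-replicate detection-limit dropout
#' (intensities only), and are closed to sum 1.
#'
#' @param cfg a [simulation_config()].
#' @return list with `intensity` (normalized [intensity_matrix()] including
#'   any control samples), `abundance` (normalized [abundance_matrix()],
#'   live bottles only), `truth` (planted links: species, formula_id,
#'   source, kind, rate), `niche_breadth` (linked-formula count per
#'   species), `annotations`, `library`, and `config`.
#' @export
simulate_microcosm <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  lib <- generate_formula_library(cfg)
  ann <- lib$annotations
  src <- lib$sources
  species <- .species_names(cfg)
  days <- cfg$days

  # one consuming species per source: specialist on source 1, generalists
  # round-robin on the rest (the first generalist covers the extra sources)
  gen_idx <- setdiff(seq_len(cfg$n_species), cfg$specialist_index)
  consumer_of <- integer(cfg$n_sources)
  consumer_of[1] <- cfg$specialist_index
  if (cfg$n_sources > 1) {
    consumer_of[-1] <- rep(gen_idx, length.out = cfg$n_sources - 1)
  }

  # even inoculum: every bottle starts from the same mixed community
  a0 <- rep(1 / cfg$n_species, cfg$n_species)

  with_seed(derive_seed(cfg$seed, 1), {
    truth <- list()
    intensity_cols <- list()
    abundance_cols <- list()
    meta <- list()
    clipped <- 0L

    for (si in seq_len(cfg$n_sources)) {
      sname <- src$source[si]
      ids <- lib$source_formulae[[sname]]
      f_ann <- ann[match(ids, ann$formula_id), ]
      x0 <- stats::rlnorm(length(ids), 0, 1)

      # planted links: one consuming species per source (the specialist on
      # its home source, otherwise one generalist); the broad generalist's
      # sources carry two target classes, so its links span classes/sources
      main <- consumer_of[si]
      broad <- gen_idx[1]
      tcls <- .target_classes(si)
      if (si > 1 && main == broad) {
        # the broad generalist specializes on the two leanest labile pools
        tcls <- c("lipid-like", "amino sugar-like")
      }
      # the broad generalist's resource use is denser as well as wider
      n_per <- if (length(tcls) > 1) {
        ceiling(1.7 * cfg$n_consumed_per_class)
      } else cfg$n_consumed_per_class
      consume_ids <- character(0)
      for (cl in tcls) {
        pool <- ids[f_ann$compound_class == cl]
        if (si == 1) pool <- ids[f_ann$compound_class == cl & f_ann$bioavailable]
        k <- min(n_per, length(pool))
        consume_ids <- c(consume_ids, sample(pool, k))
      }
      # consumed compounds are abundant constituents of their source
      x0[match(consume_ids, ids)] <- x0[match(consume_ids, ids)] *
        cfg$consumed_intensity_boost
      cons <- data.frame(
        sp = rep(main, length(consume_ids)), fi = match(consume_ids, ids),
        rate = cfg$consumption_rate * stats::runif(length(consume_ids), 0.8, 1.2))
      produce_pool <- ids[f_ann$compound_class %in%
                            c("lignin-like", "condensed aromatic-like")]
      produce_ids <- sample(produce_pool, min(cfg$n_produced, length(produce_pool)))
      prod <- data.frame(
        sp = rep(main, length(produce_ids)), fi = match(produce_ids, ids),
        rate = cfg$production_rate * stats::runif(length(produce_ids), 0.8, 1.2))
      if (nrow(cons)) {
        truth[[length(truth) + 1]] <- data.frame(
          species = species[cons$sp], formula_id = ids[cons$fi],
          source = sname, kind = "consume", rate = cons$rate,
          stringsAsFactors = FALSE)
      }
      if (nrow(prod)) {
        truth[[length(truth) + 1]] <- data.frame(
          species = species[prod$sp], formula_id = ids[prod$fi],
          source = sname, kind = "produce", rate = prod$rate,
          stringsAsFactors = FALSE)
      }

      # detection-limit dropout: probability scales with (q25 / x)^2
      apply_dropout <- function(y) {
        if (cfg$dropout_prob <= 0) return(y)
        ref <- stats::quantile(y[y > 0], 0.25, names = FALSE)
        p <- cfg$dropout_prob * pmin(1, (ref / y)^2)
        y[stats::runif(length(y)) < p] <- 0
        y
      }

      # every replicate bottle follows its own trajectory: the replicator
      # update carries per-step demographic (process) noise
      for (r in seq_len(cfg$n_replicates)) {
        x <- x0
        a <- a0
        t_prev <- 0
        for (di in seq_along(days)) {
          dt <- days[di] - t_prev
          t_prev <- days[di]
          relx <- x / sum(x)
          flux <- numeric(cfg$n_species)
          if (nrow(cons)) {
            flux_by_sp <- rowsum(cons$rate * dt * relx[cons$fi], cons$sp)
            flux[as.integer(rownames(flux_by_sp))] <- flux_by_sp
            fac <- 1 - cons$rate * dt * a[cons$sp]
            if (any(fac < 0)) clipped <- clipped + sum(fac < 0)
            fac_by_f <- exp(rowsum(log(pmax(fac, 1e-300)), cons$fi))
            fi_u <- as.integer(rownames(fac_by_f))
            x[fi_u] <- x[fi_u] * ifelse(fac_by_f <= 1e-290, 0, fac_by_f)
          }
          if (nrow(prod)) {
            gain <- rowsum(log1p(prod$rate * dt * a[prod$sp]), prod$fi)
            fi_u <- as.integer(rownames(gain))
            x[fi_u] <- x[fi_u] * exp(gain)
          }
          a <- a * (1 + cfg$growth_yield * flux)
          if (cfg$process_noise_sd > 0) {
            a <- a * exp(stats::rnorm(cfg$n_species, 0, cfg$process_noise_sd))
          }
          a <- a / sum(a)

          # sample this bottle on this day
          y <- (x / sum(x)) * rlnorm_cv(length(ids), cfg$noise_cv)
          y <- apply_dropout(y)
          if (sum(y) <= 0) stop("degenerate sample: all intensities dropped out")
          b <- a * rlnorm_cv(cfg$n_species, cfg$abundance_noise_cv)
          intensity_cols[[length(intensity_cols) + 1]] <-
            list(ids = ids, values = y / sum(y))
          abundance_cols[[length(abundance_cols) + 1]] <- b / sum(b)
          meta[[length(meta) + 1]] <- data.frame(
            sample_id = sprintf("%s_r%d_d%d", sname, r, days[di]),
            source = sname, replicate = r, day = days[di],
            is_control = FALSE, stringsAsFactors = FALSE)
        }
      }
      if (cfg$include_controls) {
        for (di in seq_along(days)) {
          y <- (x0 / sum(x0)) * rlnorm_cv(length(ids), cfg$noise_cv)
          y <- apply_dropout(y)
          intensity_cols[[length(intensity_cols) + 1]] <-
            list(ids = ids, values = y / sum(y))
          meta[[length(meta) + 1]] <- data.frame(
            sample_id = sprintf("%s_ctrl_d%d", sname, days[di]),
            source = sname, replicate = 1, day = days[di],
            is_control = TRUE, stringsAsFactors = FALSE)
        }
      }
    }

    if (clipped > 0) {
      warning(clipped, " consumption update(s) would have driven an ",
              "intensity negative; clipped at 0")
    }

    meta <- do.call(rbind, meta)
    all_ids <- sort(unique(unlist(lapply(intensity_cols, `[[`, "ids"))))
    values <- matrix(0, length(all_ids), nrow(meta),
                     dimnames = list(all_ids, meta$sample_id))
    for (j in seq_along(intensity_cols)) {
      col <- intensity_cols[[j]]
      values[col$ids, j] <- col$values
    }
    live <- !meta$is_control
    ab_values <- do.call(cbind, abundance_cols)
    dimnames(ab_values) <- list(species, meta$sample_id[live])

    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    breadth <- table(factor(truth$species, levels = species))

    list(
      intensity = intensity_matrix(values, meta, normalized = TRUE),
      abundance = abundance_matrix(ab_values, meta[live, ], normalized = TRUE),
      truth = truth,
      niche_breadth = stats::setNames(as.integer(breadth), species),
      annotations = ann,
      library = lib,
      config = cfg
    )
  })
}

#' Precision and recall of predicted consumption links
#'
#' Compares predicted (species, formula, source) links against the planted
#' consume-kind links of a simulation.
#'
#' @param predicted data.frame with columns `species`, `formula_id`,
#'   `source` (extra columns ignored).
#' @param truth planted-link table from [simulate_microcosm()].
#' @return list with `precision`, `recall`, `n_predicted`, `n_truth`,
#'   `empty_prediction` flag. Precision is reported as 0 (with the flag set)
#'   when nothing was predicted.
#' @export
recovery_metrics <- function(predicted, truth) {
  truth <- truth[truth$kind == "consume", , drop = FALSE]
  if (nrow(truth) == 0) stop("truth contains no consume links; recall undefined")
  tkey <- paste(truth$species, truth$formula_id, truth$source)
  if (is.null(predicted) || nrow(predicted) == 0) {
    return(list(precision = 0, recall = 0, n_predicted = 0L,
                n_truth = nrow(truth), empty_prediction = TRUE))
  }
  pkey <- unique(paste(predicted$species, predicted$formula_id, predicted$source))
  tp <- sum(pkey %in% tkey)
  list(precision = tp / length(pkey), recall = tp / length(tkey),
       n_predicted = length(pkey), n_truth = length(tkey),
       empty_prediction = FALSE)
}
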