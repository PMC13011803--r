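#' Configuration of the end-to-end analysis pipeline
#'
#' Either point `input` at the CSV interfaces of an existing dataset, or
#' leave it `NULL` to run in synthetic mode on a [simulation_config()].
#'
#' @param input `NULL`, or a list with paths `formula_csv`,
#'   `intensity_csv`, `metadata_csv`, and optionally `abundance_csv`.
#' @param simulation a [simulation_config()] used when `input` is `NULL`.
#' @param time_fraction two-sided selection fraction of the formula-by-time
#'   screen (default 0.05).
#' @param species_fraction one-sided negative fraction of the
#'   species-by-formula screen (default 0.025).
#' @param time_neg_fraction one-sided negative fraction of the
#'   time-declining set used by the joint screen (default 0.025).
#' @param alpha significance level for enrichment verdicts (default 0.05).
#' @param n_perm permutations for all permutation tests (default 999).
#' @param min_reps replicate presence rule (default 2).
#' @param dbrda_target positive-inertia coverage of the dbRDA predictor
#'   axes (default 0.9).
#' @param seed root seed; every stochastic stage derives its own seed from
#'   it.
#' @param outdir optional output directory; when set, all stage tables, a
#'   JSON run report and a YAML echo of the resolved configuration are
#'   written there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulation = simulation_config(),
                            time_fraction = 0.05, species_fraction = 0.025,
                            time_neg_fraction = 0.025, alpha = 0.05,
                            n_perm = 999, min_reps = 2, dbrda_target = 0.9,
                            seed = 1, outdir = NULL) {
  if (is.null(input) && is.null(simulation)) {
    stop("either `input` paths or a `simulation` config must be given")
  }
  structure(list(input = input, simulation = simulation,
                 time_fraction = time_fraction,
                 species_fraction = species_fraction,
                 time_neg_fraction = time_neg_fraction, alpha = alpha,
                 n_perm = n_perm, min_reps = min_reps,
                 dbrda_target = dbrda_target, seed = seed, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full microbe-DOM coupling pipeline
#'
#' Stage order: (optional) simulate -> chemistry (TIC normalization,
#' replicate presence filter, bulk metrics) -> community analyses
#' (Bray-Curtis, PCoA for DOM and bacteria, PERMANOVA by source, envfit of
#' bulk metrics, Procrustes/PROTEST, dbRDA of bacterial composition on DOM
#' axes) -> formula-by-time enrichment screen -> species resource-use and
#' joint-depletion screens (plus planted-truth recovery in synthetic mode).
#' Control samples are carried through the chemistry stage but excluded
#' from all correlation screens and community tests.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_report` list with every stage's result, the realized
#'   cutoffs, per-stage seeds, and captured warnings.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  warnings_log <- character(0)
  catch <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log[[length(warnings_log) + 1]] <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  }
  seeds <- list(simulate = derive_seed(cfg$seed, 100),
                permanova_dom = derive_seed(cfg$seed, 200),
                permanova_bact = derive_seed(cfg$seed, 201),
                envfit = derive_seed(cfg$seed, 202),
                procrustes = derive_seed(cfg$seed, 203),
                dbrda = derive_seed(cfg$seed, 204),
                enrichment = derive_seed(cfg$seed, 300),
                species_test = derive_seed(cfg$seed, 400))

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (is.null(cfg$input)) {
    sim_cfg <- cfg$simulation
    sim_cfg$seed <- seeds$simulate
    sim <- catch(simulate_microcosm(sim_cfg))
    intensity <- sim$intensity
    abundance <- sim$abundance
    annotations <- sim$annotations
    truth <- sim$truth
  } else {
    tabs <- read_tables(cfg$input$formula_csv, cfg$input$intensity_csv,
                        cfg$input$metadata_csv, cfg$input$abundance_csv)
    intensity <- normalize_tic(tabs$intensity)
    abundance <- if (!is.null(tabs$abundance)) normalize_tic(tabs$abundance)
    annotations <- annotate_formulae(tabs$formula_table)
  }

  # --- chemistry ----------------------------------------------------------
  intensity <- catch(replicate_presence_filter(intensity, cfg$min_reps))
  bulk <- bulk_metrics(intensity, annotations)

  # --- community analyses -------------------------------------------------
  live <- drop_controls(intensity)
  dom_bc <- bray_curtis(live)
  dom_ord <- catch(pcoa(dom_bc))
  perman_dom <- permanova(dom_bc, data.frame(source = live$samples$source),
                          n_perm = cfg$n_perm, seed = seeds$permanova_dom)
  bulk_live <- bulk[!bulk$is_control, ]
  fit_vars <- bulk_live[, c("weighted_hc", "weighted_oc", "weighted_aimod",
                            "weighted_mass", "bioavailable_fraction")]
  dom_envfit <- envfit_vectors(dom_ord, fit_vars, n_perm = cfg$n_perm,
                               seed = seeds$envfit)
  bact <- list(ord = NULL, permanova = NULL, procrustes = NULL, dbrda = NULL)
  if (!is.null(abundance)) {
    shared <- intersect(sample_ids(live), sample_ids(abundance))
    ab <- subset_samples(abundance, match(shared, sample_ids(abundance)))
    dom_shared <- subset_samples(live, match(shared, sample_ids(live)))
    bact_bc <- bray_curtis(ab)
    bact$ord <- catch(pcoa(bact_bc))
    bact$permanova <- permanova(bact_bc,
                                data.frame(source = ab$samples$source),
                                n_perm = cfg$n_perm,
                                seed = seeds$permanova_bact)
    dom_ord_shared <- catch(pcoa(bray_curtis(dom_shared)))
    bact$procrustes <- procrustes_protest(dom_ord_shared, bact$ord,
                                          n_perm = cfg$n_perm,
                                          seed = seeds$procrustes)
    bact$dbrda <- dbrda(bact_bc,
                        pcoa_predictors(dom_ord_shared, cfg$dbrda_target),
                        n_perm = cfg$n_perm, seed = seeds$dbrda)
  }

  # --- temporal enrichment ------------------------------------------------
  time_corrs <- catch(correlate_time(intensity, min_reps = cfg$min_reps))
  time_thr <- percentile_threshold(time_corrs, cfg$time_fraction, "two")
  enrichment <- class_enrichment(time_thr, annotations, alpha = cfg$alpha,
                                 seed = seeds$enrichment)

  # --- resource use -------------------------------------------------------
  resource <- list(profile = NULL, species_test = NULL, joint = NULL,
                   recovery = NULL)
  if (!is.null(abundance)) {
    sp_corrs <- catch(correlate_species(abundance, intensity))
    sp_thr <- percentile_threshold(sp_corrs, cfg$species_fraction, "negative")
    resource$profile <- catch(putative_use(sp_thr, annotations))
    resource$species_test <- species_difference_test(
      resource$profile, n_perm = cfg$n_perm, seed = seeds$species_test)
    time_neg <- percentile_threshold(time_corrs, cfg$time_neg_fraction,
                                     "negative")
    resource$joint <- joint_depletion(sp_thr, time_neg)
    if (!is.null(truth)) {
      resource$recovery <- recovery_metrics(resource$joint$links, truth)
    }
  }

  report <- structure(list(
    config = cfg, seeds = seeds, annotations = annotations,
    intensity = intensity, abundance = abundance, truth = truth,
    bulk_metrics = bulk, dom_ordination = dom_ord,
    dom_permanova = perman_dom, dom_envfit = dom_envfit,
    bact_ordination = bact$ord, bact_permanova = bact$permanova,
    procrustes = bact$procrustes, dbrda = bact$dbrda,
    time_correlations = time_thr, enrichment = enrichment,
    resource_use = resource,
    realized_cutoffs = list(
      time_two_sided = attr(time_thr, "realized_cutoff"),
      species_negative = if (!is.null(resource$profile))
        resource$profile$realized_cutoff,
      time_negative = if (!is.null(resource$joint))
        resource$joint$time_cutoff),
    warnings = warnings_log), class = "pipeline_report")

  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  DOM PERMANOVA by source: F = %.2f, p = %.4g\n",
              x$dom_permanova$pseudo_F, x$dom_permanova$p_value))
  if (!is.null(x$procrustes)) {
    cat(sprintf("  Procrustes m2 = %.3f (p = %.4g); dbRDA R2 = %.3f\n",
                x$procrustes$m2, x$procrustes$p_value, x$dbrda$R2))
  }
  cat(sprintf("  time screen cutoff |rho| >= %.3f; %d enrichment verdicts\n",
              x$realized_cutoffs$time_two_sided,
              sum(x$enrichment$verdict != "none")))
  if (!is.null(x$resource_use$recovery)) {
    cat(sprintf("  planted-link recovery: precision %.2f, recall %.2f\n",
                x$resource_use$recovery$precision,
                x$resource_use$recovery$recall))
  }
  invisible(x)
}

#' Write pipeline outputs, a JSON report, and a YAML config echo
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], signif, digits = 10)
    df
  }
  wcsv <- function(df, name) {
    utils::write.csv(sig(as.data.frame(df)), file.path(dir, name),
                     row.names = FALSE)
  }
  wcsv(report$bulk_metrics, "bulk_metrics.csv")
  wcsv(cbind(sample_id = rownames(report$dom_ordination$coords),
             as.data.frame(report$dom_ordination$coords[, 1:min(4,
               ncol(report$dom_ordination$coords))])), "dom_pcoa.csv")
  wcsv(report$time_correlations, "correlations.csv")
  wcsv(report$enrichment, "enrichment.csv")
  if (!is.null(report$resource_use$profile)) {
    wcsv(report$resource_use$profile$profile, "profile.csv")
    wcsv(report$resource_use$joint$per_cell, "joint.csv")
  }
  if (!is.null(report$truth)) wcsv(report$truth, "truth.csv")
  summary <- list(
    dom_permanova = list(pseudo_F = report$dom_permanova$pseudo_F,
                         R2 = report$dom_permanova$R2,
                         p = report$dom_permanova$p_value,
                         n_perm = report$dom_permanova$n_permutations),
    bact_permanova = if (!is.null(report$bact_permanova)) list(
      pseudo_F = report$bact_permanova$pseudo_F,
      R2 = report$bact_permanova$R2, p = report$bact_permanova$p_value),
    procrustes = if (!is.null(report$procrustes)) list(
      m2 = report$procrustes$m2, protest_r = report$procrustes$protest_r,
      p = report$procrustes$p_value),
    dbrda = if (!is.null(report$dbrda)) list(
      R2 = report$dbrda$R2, pseudo_F = report$dbrda$pseudo_F,
      p = report$dbrda$p_value),
    realized_cutoffs = report$realized_cutoffs,
    recovery = report$resource_use$recovery,
    seeds = report$seeds,
    warnings = report$warnings)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- report$config
  cfg_list <- unclass(cfg)
  cfg_list$simulation <- if (!is.null(cfg$simulation)) unclass(cfg$simulation)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(dir)
}
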