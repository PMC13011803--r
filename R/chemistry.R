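#' Molecular formula chemistry
#'
#' Tools to annotate CHNOSP molecular formulae with the metrics used to
#' characterize dissolved organic matter on the van Krevelen plane: the
#' H/C ratio (degree of saturation; values >= 1.5 mark biolabile formulae),
#' the O/C ratio (oxidation state), the modified aromaticity index AI_mod,
#' the neutral monoisotopic mass, and a putative compound class.
#'
#' @name dom-chemistry
NULL

# monoisotopic atomic masses (Da)
.MONO_MASS <- c(c = 12.000000, h = 1.0078250319, n = 14.0030740052,
                o = 15.9949146221, s = 31.97207069, p = 30.97376151)

# mass of a proton; subtracted to convert neutral mass to [M-H]- m/z
.PROTON_MASS <- 1.00728

.ELEMENTS <- c("c", "h", "n", "o", "s", "p")

#' Parse molecular formula strings
#'
#' Accepts Hill-order style strings over C, H, N, O, S, P, e.g. `"C10H12O5"`
#' or `"C6H13NO2S"`. An element symbol without a count means count 1.
#'
#' @param x character vector of formula strings.
#' @return data.frame with integer columns `c, h, n, o, s, p`.
#' @examples
#' parse_molecular_formula(c("C6H12O6", "CH4"))
#' @export
parse_molecular_formula <- function(x) {
  stopifnot(is.character(x))
  out <- matrix(0L, nrow = length(x), ncol = 6,
                dimnames = list(NULL, .ELEMENTS))
  for (i in seq_along(x)) {
    s <- x[i]
    m <- gregexpr("([CHNOSP])([0-9]*)", s, perl = TRUE)[[1]]
    if (m[1] == -1L) stop("cannot parse formula string: ", s)
    toks <- regmatches(s, gregexpr("([CHNOSP])([0-9]*)", s, perl = TRUE))[[1]]
    if (nchar(paste(toks, collapse = "")) != nchar(s)) {
      stop("formula string contains unsupported symbols: ", s)
    }
    for (tok in toks) {
      el <- tolower(substr(tok, 1, 1))
      cnt <- substr(tok, 2, nchar(tok))
      out[i, el] <- out[i, el] + if (nchar(cnt)) as.integer(cnt) else 1L
    }
  }
  as.data.frame(out)
}

#' Van Krevelen compound-class decision table
#'
#' Rectangles in the (H/C, O/C) plane, applied top to bottom; the first
#' matching rectangle wins, and formulae matching none are `unassigned`.
#' Bounds are closed/open as encoded in the `*_incl` columns.
#'
#' @return data.frame with one rule per row: `class`, `hc_lo`, `hc_hi`,
#'   `oc_lo`, `oc_hi` and inclusivity flags `hc_lo_incl`, `hc_hi_incl`,
#'   `oc_lo_incl`, `oc_hi_incl`.
#' @export
vk_class_table <- function() {
  data.frame(
    class = c("lipid-like", "protein-like", "amino sugar-like",
              "carbohydrate-like", "unsaturated hydrocarbon-like",
              "lignin-like", "tannin-like", "condensed aromatic-like"),
    hc_lo = c(1.5, 1.5, 1.5, 1.5, 0.7, 0.7, 0.5, 0.2),
    hc_hi = c(2.0, 2.2, 2.2, 2.4, 1.5, 1.5, 1.5, 0.7),
    hc_lo_incl = TRUE,
    hc_hi_incl = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    oc_lo = c(0, 0.3, 0.55, 0.7, 0, 0.1, 0.67, 0),
    oc_hi = c(0.3, 0.55, 0.7, 1.2, 0.1, 0.67, 0.97, 0.67),
    oc_lo_incl = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    oc_hi_incl = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Assign putative compound classes from van Krevelen position
#'
#' @param hc,oc numeric vectors of H/C and O/C ratios (`hc > 0`, `oc >= 0`).
#' @param table decision table, by default [vk_class_table()].
#' @return character vector of class labels (`"unassigned"` when no
#'   rectangle matches).
#' @examples
#' assign_compound_class(c(2.0, 1.0, 0.5), c(1.0, 0.3, 0.2))
#' @export
assign_compound_class <- function(hc, oc, table = vk_class_table()) {
  stopifnot(length(hc) == length(oc), all(hc > 0), all(oc >= 0))
  cls <- rep("unassigned", length(hc))
  undecided <- rep(TRUE, length(hc))
  for (r in seq_len(nrow(table))) {
    lo_h <- if (table$hc_lo_incl[r]) hc >= table$hc_lo[r] else hc > table$hc_lo[r]
    hi_h <- if (table$hc_hi_incl[r]) hc <= table$hc_hi[r] else hc < table$hc_hi[r]
    lo_o <- if (table$oc_lo_incl[r]) oc >= table$oc_lo[r] else oc > table$oc_lo[r]
    hi_o <- if (table$oc_hi_incl[r]) oc <= table$oc_hi[r] else oc < table$oc_hi[r]
    hit <- undecided & lo_h & hi_h & lo_o & hi_o
    cls[hit] <- table$class[r]
    undecided <- undecided & !hit
  }
  cls
}

#' Annotate molecular formulae with derived chemistry
#'
#' Computes, per formula: H/C and O/C ratios, the modified aromaticity index
#' AI_mod = (1 + C - O/2 - S - (N + H)/2) / (C - O/2 - S - N - P), the
#' neutral monoisotopic mass, the compound class, and the biolability flag
#' (H/C >= `bioavailable_cutoff`). AI_mod is reported as 0 when the raw
#' value is negative or the denominator is non-positive, and capped at 1,
#' keeping it on its interpretable [0, 1] scale.
#'
#' @param formulas either a character vector of formula strings (parsed with
#'   [parse_molecular_formula()]) or a data.frame with integer columns
#'   `c, h, n, o, s, p` and optionally `formula_id`.
#' @param bioavailable_cutoff H/C cutoff for the biolabile flag (default 1.5).
#' @param class_table compound-class decision table, see [vk_class_table()].
#' @return data.frame with columns `formula_id`, `c, h, n, o, s, p`,
#'   `neutral_mass`, `hc`, `oc`, `ai_mod`, `compound_class`, `bioavailable`.
#' @examples
#' annotate_formulae(c("C6H6", "C6H12O6", "CH4"))
#' @export
annotate_formulae <- function(formulas, bioavailable_cutoff = 1.5,
                              class_table = vk_class_table()) {
  if (is.character(formulas)) {
    df <- parse_molecular_formula(formulas)
    df$formula_id <- formulas
  } else {
    df <- as.data.frame(formulas)
    missing <- setdiff(.ELEMENTS, names(df))
    if (length(missing)) {
      stop("formula table lacks element column(s): ",
           paste(missing, collapse = ", "))
    }
    if (is.null(df$formula_id)) {
      df$formula_id <- sprintf("F%05d", seq_len(nrow(df)))
    }
  }
  counts <- as.matrix(df[, .ELEMENTS])
  if (any(counts != round(counts)) || any(counts < 0) || any(!is.finite(counts))) {
    stop("element counts must be finite non-negative integers")
  }
  bad <- counts[, "c"] < 1 | counts[, "h"] < 1
  if (any(bad)) {
    stop("invalid formula (needs C >= 1 and H >= 1): ",
         paste(df$formula_id[bad], collapse = ", "))
  }
  C <- counts[, "c"]; H <- counts[, "h"]; N <- counts[, "n"]
  O <- counts[, "o"]; S <- counts[, "s"]; P <- counts[, "p"]
  num <- 1 + C - 0.5 * O - S - 0.5 * (N + H)
  den <- C - 0.5 * O - S - N - P
  ai <- ifelse(den <= 0, 0, num / den)
  ai <- pmin(pmax(ai, 0), 1)
  hc <- H / C
  oc <- O / C
  data.frame(
    formula_id = as.character(df$formula_id),
    c = C, h = H, n = N, o = O, s = S, p = P,
    neutral_mass = as.numeric(counts %*% .MONO_MASS[.ELEMENTS]),
    hc = hc, oc = oc, ai_mod = ai,
    compound_class = assign_compound_class(hc, oc, class_table),
    bioavailable = hc >= bioavailable_cutoff,
    stringsAsFactors = FALSE
  )
}

#' Neutral mass to negative-mode m/z
#'
#' Convenience conversion to the deprotonated ion mass; the pipeline itself
#' works with neutral masses throughout.
#'
#' @param neutral_mass numeric vector of neutral monoisotopic masses (Da).
#' @return m/z of \[M-H\]^- ions.
#' @export
neutral_to_mz_neg <- function(neutral_mass) neutral_mass - .PROTON_MASS

#' Normalize peak intensities to the sample total (TIC normalization)
#'
#' Divides every sample column by its own total so intensities become
#' relative (compositional); idempotent.
#'
#' @param m an `intensity_matrix` (or `abundance_matrix`).
#' @return the same class of matrix with `normalized = TRUE`.
#' @export
normalize_tic <- function(m) {
  stopifnot(inherits(m, "sample_matrix"))
  cs <- colSums(m$values)
  if (any(cs <= 0)) {
    bad <- m$samples[cs <= 0, c("source", "replicate", "day")]
    stop("sample(s) with zero total intensity: ",
         paste(sprintf("(%s, rep %s, day %s)", bad$source, bad$replicate, bad$day),
               collapse = "; "))
  }
  values <- sweep(m$values, 2, cs, "/")
  new_sample_matrix(values, m$samples, TRUE, class(m)[1])
}

#' Replicate presence filter
#'
#' Within each (source, day) replicate group, keep a formula's intensities
#' only when it is present (intensity > 0) in at least `min_reps` replicates
#' of that group; otherwise zero it for that whole group. Columns are
#' re-normalized afterwards. Control samples form their own groups.
#'
#' @param m an `intensity_matrix`.
#' @param min_reps minimum number of replicates a formula must appear in
#'   (default 2, "at least two of three replicates").
#' @param renormalize re-apply TIC normalization after zeroing (default TRUE).
#' @return filtered `intensity_matrix`.
#' @export
replicate_presence_filter <- function(m, min_reps = 2, renormalize = TRUE) {
  stopifnot(inherits(m, "sample_matrix"), min_reps >= 1)
  values <- m$values
  grp <- interaction(m$samples$source, m$samples$day, m$samples$is_control,
                     drop = TRUE)
  for (g in levels(grp)) {
    cols <- which(grp == g)
    if (length(cols) < min_reps) {
      warning("replicate group ", g, " has fewer than ", min_reps,
              " replicates; passed through unfiltered")
      next
    }
    present <- rowSums(values[, cols, drop = FALSE] > 0)
    values[present < min_reps, cols] <- 0
  }
  out <- new_sample_matrix(values, m$samples, FALSE, class(m)[1])
  if (renormalize) normalize_tic(out) else out
}

#' Intensity-weighted bulk DOM metrics per sample
#'
#' For each sample: intensity-weighted mean H/C, O/C, AI_mod and neutral
#' mass; the summed relative intensity of biolabile formulae
#' (H/C >= cutoff); and the summed relative intensity per compound class.
#'
#' @param m a normalized `intensity_matrix`.
#' @param annotations annotation table from [annotate_formulae()]; must cover
#'   every row of `m`.
#' @return data.frame with one row per sample: the sample key columns,
#'   `weighted_hc`, `weighted_oc`, `weighted_aimod`, `weighted_mass`,
#'   `bioavailable_fraction`, then one `class_*` fraction column per
#'   compound class present in the annotations.
#' @export
bulk_metrics <- function(m, annotations) {
  stopifnot(inherits(m, "sample_matrix"))
  if (!m$normalized) stop("`m` must be TIC-normalized; see normalize_tic()")
  ids <- rownames(m$values)
  hit <- match(ids, annotations$formula_id)
  if (anyNA(hit)) {
    stop("annotation missing for formula id(s): ",
         paste(utils::head(ids[is.na(hit)], 10), collapse = ", "))
  }
  ann <- annotations[hit, ]
  w <- m$values  # columns sum to 1
  out <- m$samples
  out$weighted_hc <- as.numeric(crossprod(w, ann$hc))
  out$weighted_oc <- as.numeric(crossprod(w, ann$oc))
  out$weighted_aimod <- as.numeric(crossprod(w, ann$ai_mod))
  out$weighted_mass <- as.numeric(crossprod(w, ann$neutral_mass))
  out$bioavailable_fraction <- as.numeric(crossprod(w, as.numeric(ann$bioavailable)))
  for (cl in sort(unique(ann$compound_class))) {
    col <- paste0("class_", gsub("[^a-z]+", "_", cl))
    out[[col]] <- colSums(w[ann$compound_class == cl, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
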