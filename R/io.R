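#' Read the tabular interfaces into typed matrices
#'
#' Reads the three (or four) CSV interfaces: a formula table
#' (`formula_id, c, h, n, o, s, p` or a `formula` string column), a long
#' intensity table (`formula_id, source, replicate, day, intensity`;
#' omitted combinations are zeros), a sample metadata table
#' (`source, replicate, day, is_control`), and optionally a long abundance
#' table (`species, source, replicate, day, abundance`). All schema
#' violations are collected and reported together, not first-failure-only.
#'
#' @param formula_csv,intensity_csv,metadata_csv,abundance_csv file paths;
#'   `abundance_csv` may be `NULL`.
#' @param days_allowed admissible sampling days (default `c(1, 4, 7, 14)`;
#'   override for other designs).
#' @return list with `intensity` (raw [intensity_matrix()]), `abundance`
#'   ([abundance_matrix()] or `NULL`), `formula_table` (element counts),
#'   `metadata`.
#' @export
read_tables <- function(formula_csv, intensity_csv, metadata_csv,
                        abundance_csv = NULL, days_allowed = c(1, 4, 7, 14)) {
  errs <- character(0)
  note <- function(...) errs[[length(errs) + 1]] <<- paste0(...)

  fm <- utils::read.csv(formula_csv, stringsAsFactors = FALSE)
  if ("formula" %in% names(fm) && !all(.ELEMENTS %in% names(fm))) {
    counts <- parse_molecular_formula(fm$formula)
    fm <- cbind(fm["formula_id"], counts)
  }
  if (!"formula_id" %in% names(fm)) note("formula table: missing formula_id")
  miss <- setdiff(.ELEMENTS, names(fm))
  if (length(miss)) note("formula table: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (!length(errs) && anyDuplicated(fm$formula_id)) {
    note("formula table: duplicate formula_id")
  }

  md <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  need <- c("source", "replicate", "day")
  miss <- setdiff(need, names(md))
  if (length(miss)) note("metadata: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (!"is_control" %in% names(md)) md$is_control <- FALSE
  md$is_control <- as.logical(md$is_control)
  if (!length(miss)) {
    bad_day <- setdiff(unique(md$day), days_allowed)
    if (length(bad_day)) {
      note("metadata: day value(s) not in {",
           paste(days_allowed, collapse = ","), "}: ",
           paste(bad_day, collapse = ", "))
    }
    key <- paste(md$source, md$replicate, md$day, md$is_control)
    if (anyDuplicated(key)) note("metadata: duplicate (source, replicate, day) rows")
  }

  it <- utils::read.csv(intensity_csv, stringsAsFactors = FALSE)
  need_it <- c("formula_id", "source", "replicate", "day", "intensity")
  miss <- setdiff(need_it, names(it))
  if (length(miss)) note("intensity table: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (!length(miss)) {
    if (any(it$intensity < 0)) note("intensity table: negative intensities")
    dup_cols <- intersect(c("formula_id", "source", "replicate", "day",
                            "is_control"), names(it))
    if (anyDuplicated(it[, dup_cols])) {
      note("intensity table: duplicate (formula, sample) rows")
    }
    if (!"formula_id" %in% names(fm) || !all(it$formula_id %in% fm$formula_id)) {
      unk <- setdiff(unique(it$formula_id), fm$formula_id)
      if (length(unk)) note("intensity table: formula_id not in formula table: ",
                            paste(utils::head(unk, 5), collapse = ", "))
    }
  }

  ab <- NULL
  if (!is.null(abundance_csv)) {
    ab <- utils::read.csv(abundance_csv, stringsAsFactors = FALSE)
    need_ab <- c("species", "source", "replicate", "day", "abundance")
    miss <- setdiff(need_ab, names(ab))
    if (length(miss)) note("abundance table: missing column(s) ",
                           paste(miss, collapse = ", "))
    if (!length(miss) && any(ab$abundance < 0)) {
      note("abundance table: negative abundances")
    }
  }
  if (length(errs)) stop("schema violations:\n  - ",
                         paste(errs, collapse = "\n  - "))

  if (!"is_control" %in% names(md)) md$is_control <- FALSE
  md$sample_id <- ifelse(md$is_control,
                         sprintf("%s_ctrl_d%d", md$source, md$day),
                         sprintf("%s_r%d_d%d", md$source, md$replicate, md$day))
  build <- function(long, feature_col, value_col, features, controls_ok) {
    meta <- if (controls_ok) md else md[!md$is_control, , drop = FALSE]
    meta <- meta[order(meta$source, meta$day, meta$replicate), , drop = FALSE]
    rownames(meta) <- NULL
    long$sample_id <- sprintf("%s_r%d_d%d", long$source, long$replicate,
                              long$day)
    if (controls_ok && "is_control" %in% names(long)) {
      ctrl <- as.logical(long$is_control)
      long$sample_id[ctrl] <- sprintf("%s_ctrl_d%d", long$source[ctrl],
                                      long$day[ctrl])
    }
    vals <- matrix(0, length(features), nrow(meta),
                   dimnames = list(features, meta$sample_id))
    hit_r <- match(long[[feature_col]], features)
    hit_c <- match(long$sample_id, meta$sample_id)
    keep <- !is.na(hit_r) & !is.na(hit_c)
    vals[cbind(hit_r[keep], hit_c[keep])] <- long[[value_col]][keep]
    list(values = vals, meta = meta)
  }
  bi <- build(it, "formula_id", "intensity", unique(fm$formula_id), TRUE)
  intensity <- intensity_matrix(bi$values, bi$meta, normalized = FALSE)
  abundance <- NULL
  if (!is.null(ab)) {
    ba <- build(ab, "species", "abundance", unique(ab$species), FALSE)
    abundance <- abundance_matrix(ba$values, ba$meta, normalized = FALSE)
  }
  list(intensity = intensity, abundance = abundance, formula_table = fm,
       metadata = md)
}

#' Write a simulated (or assembled) dataset as the CSV interfaces
#'
#' Writes `formulae.csv`, `intensity.csv` (long, nonzero entries),
#' `metadata.csv`, `abundance.csv` and, when planted truth is present,
#' `truth.csv`; floats are written at 10 significant digits.
#'
#' @param sim result of [simulate_microcosm()], or a list with `intensity`,
#'   `abundance`, `annotations` (and optionally `truth`).
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], signif, digits = 10)
    df
  }
  files <- character(0)
  out <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(sig(df), path, row.names = FALSE, quote = FALSE)
    files[[length(files) + 1]] <<- path
  }
  ann <- sim$annotations
  out(ann[, c("formula_id", .ELEMENTS)], "formulae.csv")
  m <- sim$intensity
  nz <- which(m$values > 0, arr.ind = TRUE)
  long <- data.frame(
    formula_id = rownames(m$values)[nz[, 1]],
    source = m$samples$source[nz[, 2]],
    replicate = m$samples$replicate[nz[, 2]],
    day = m$samples$day[nz[, 2]],
    is_control = m$samples$is_control[nz[, 2]],
    intensity = m$values[nz])
  out(long[order(long$source, long$day, long$replicate, long$formula_id), ],
      "intensity.csv")
  out(m$samples[, c("source", "replicate", "day", "is_control")],
      "metadata.csv")
  if (!is.null(sim$abundance)) {
    a <- sim$abundance
    long_a <- data.frame(
      species = rep(rownames(a$values), ncol(a$values)),
      source = rep(a$samples$source, each = nrow(a$values)),
      replicate = rep(a$samples$replicate, each = nrow(a$values)),
      day = rep(a$samples$day, each = nrow(a$values)),
      abundance = as.numeric(a$values))
    out(long_a, "abundance.csv")
  }
  if (!is.null(sim$truth)) out(sim$truth, "truth.csv")
  invisible(unlist(files))
}
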