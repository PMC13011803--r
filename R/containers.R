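#' Sample metadata and matrix containers
#'
#' An intensity matrix holds molecular formulae (rows) by samples (columns)
#' with per-sample metadata keyed by (source, replicate, day). An abundance
#' matrix holds species (rows) by the same sample keys. Both are plain lists
#' with a class attribute; values are base matrices so all downstream linear
#' algebra stays in base R.
#'
#' @param values numeric matrix, rows = features (formulae or species),
#'   columns = samples; rownames and colnames required.
#' @param samples data.frame with columns `sample_id`, `source`, `replicate`,
#'   `day` and optionally `is_control` (default `FALSE`). `sample_id` must
#'   match `colnames(values)` in order.
#' @param normalized logical; `TRUE` when every column sums to 1.
#' @return An object of class `intensity_matrix` or `abundance_matrix`
#'   (both inherit `sample_matrix`): a list with elements `values`,
#'   `samples`, `normalized`.
#' @export
intensity_matrix <- function(values, samples, normalized = FALSE) {
  new_sample_matrix(values, samples, normalized, "intensity_matrix")
}

#' @rdname intensity_matrix
#' @export
abundance_matrix <- function(values, samples, normalized = FALSE) {
  new_sample_matrix(values, samples, normalized, "abundance_matrix")
}

new_sample_matrix <- function(values, samples, normalized, subclass) {
  stopifnot(is.matrix(values), is.numeric(values), is.data.frame(samples))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (features) and colnames (sample ids)")
  }
  required <- c("sample_id", "source", "replicate", "day")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    stop("sample metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"is_control" %in% names(samples)) samples$is_control <- FALSE
  if (!identical(as.character(samples$sample_id), colnames(values))) {
    stop("`samples$sample_id` must equal colnames(values), in order")
  }
  key <- paste(samples$source, samples$replicate, samples$day, samples$is_control)
  if (anyDuplicated(key)) {
    stop("duplicate (source, replicate, day) sample keys: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("matrix values must be finite and non-negative")
  }
  if (normalized) {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9)) {
      stop("normalized = TRUE but some columns do not sum to 1 (max dev ",
           format(max(abs(cs - 1))), ")")
    }
  }
  structure(
    list(values = values, samples = samples, normalized = isTRUE(normalized)),
    class = c(subclass, "sample_matrix")
  )
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d features x %d samples (%s)\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw"))
  cat("sources:", paste(unique(x$samples$source), collapse = ", "), "\n")
  cat("days:", paste(sort(unique(x$samples$day)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a sample matrix by sample index
#'
#' @param m a `sample_matrix`.
#' @param idx logical or integer index over samples (columns).
#' @return A `sample_matrix` of the same class. The normalized flag is kept:
#'   subsetting drops whole columns, so column sums are unchanged.
#' @export
subset_samples <- function(m, idx) {
  stopifnot(inherits(m, "sample_matrix"))
  values <- m$values[, idx, drop = FALSE]
  samples <- m$samples[idx, , drop = FALSE]
  rownames(samples) <- NULL
  new_sample_matrix(values, samples, m$normalized, class(m)[1])
}

#' Drop no-bacteria control samples
#'
#' @param m a `sample_matrix`.
#' @return `m` restricted to samples with `is_control == FALSE`.
#' @export
drop_controls <- function(m) {
  subset_samples(m, !m$samples$is_control)
}

sample_ids <- function(m) as.character(m$samples$sample_id)
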