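#' Spearman rank correlation (midrank Pearson)
#'
#' Pearson correlation of average ranks; ties receive midranks. Returns
#' `NA` for constant series (an undefined correlation, excluded downstream
#' rather than propagated).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\], or `NA_real_` when either series is constant.
#' @examples
#' spearman_rho(c(1, 4, 7, 14), c(0.1, 0.2, 0.3, 0.4))
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x)
  ry <- rank(y)
  rx <- rx - mean(rx)
  ry <- ry - mean(ry)
  den <- sqrt(sum(rx^2) * sum(ry^2))
  if (den == 0) return(NA_real_)
  sum(rx * ry) / den
}

# rank rows of a matrix (midranks), center, and return with row norms
.rank_center_rows <- function(X) {
  R <- t(apply(X, 1, rank))
  if (nrow(X) == 1) R <- matrix(R, nrow = 1)
  R <- R - rowMeans(R)
  list(R = R, norm = sqrt(rowSums(R^2)))
}

#' Formula-by-time Spearman correlations per DOM source
#'
#' For each source, correlates every eligible formula's relative intensity
#' with the sampling day over all replicate samples of that source pooled
#' (day is the x variable, so 3 replicates x 4 days gives 12 points with
#' tied x handled by midranks). Eligibility follows the presence rule: the
#' formula must be present (> 0) in at least `min_reps` replicates at every
#' time point of that source. Control samples are excluded. Formulae with a
#' constant series are excluded as undefined, not zero-filled.
#'
#' @param m a normalized (and typically replicate-filtered)
#'   [intensity_matrix()].
#' @param min_reps presence rule threshold per time point (default 2).
#' @return data.frame of class `correlation_table`: `formula_id`, `source`,
#'   `rho`, `n_points`. Excluded-as-constant counts are kept in
#'   `attr(, "n_undefined")`.
#' @export
correlate_time <- function(m, min_reps = 2) {
  stopifnot(inherits(m, "sample_matrix"))
  if (!m$normalized) stop("`m` must be normalized")
  m <- drop_controls(m)
  out <- list()
  n_undefined <- 0L
  for (s in unique(m$samples$source)) {
    cols <- which(m$samples$source == s)
    days <- m$samples$day[cols]
    if (length(unique(days)) < 2) {
      warning("source ", s, " has fewer than 2 time points; skipped")
      next
    }
    V <- m$values[, cols, drop = FALSE]
    present <- sapply(sort(unique(days)), function(d) {
      rowSums(V[, days == d, drop = FALSE] > 0)
    })
    if (!is.matrix(present)) present <- matrix(present, nrow = nrow(V))
    eligible <- rowSums(present >= min_reps) == length(unique(days))
    if (!any(eligible)) next
    V <- V[eligible, , drop = FALSE]
    rc <- .rank_center_rows(V)
    rd <- rank(days) - mean(rank(days))
    rho <- as.numeric(rc$R %*% rd) / (rc$norm * sqrt(sum(rd^2)))
    ok <- rc$norm > 0
    n_undefined <- n_undefined + sum(!ok)
    out[[length(out) + 1]] <- data.frame(
      formula_id = rownames(V)[ok], source = s, rho = rho[ok],
      n_points = length(cols), stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(formula_id = character(0), source = character(0),
               rho = numeric(0), n_points = integer(0))
  rownames(res) <- NULL
  attr(res, "n_undefined") <- n_undefined
  class(res) <- c("correlation_table", class(res))
  res
}

#' Percentile threshold on a pooled correlation table
#'
#' Realizes the study's "top f of all correlations" rule as an order
#' statistic of the pooled correlations in scope: two-sided thresholds use
#' the k-th largest |rho| (k = ceiling(f * N)) and select |rho| >= cutoff
#' (ties at the cutoff are all kept); one-sided negative thresholds use the
#' k-th smallest rho and select rho <= cutoff.
#'
#' @param corrs a correlation table (data.frame with a `rho` column).
#' @param top_fraction fraction to select (e.g. 0.05 two-sided, 0.025
#'   one-sided negative).
#' @param sided `"two"` (on |rho|) or `"negative"` (on signed rho).
#' @param scope `"dataset"` pools everything; `"per-source"` thresholds each
#'   source separately.
#' @return the table with logical columns `selected_pos`, `selected_neg`
#'   added; the realized cutoff(s) in `attr(, "realized_cutoff")`, plus
#'   `attr(, "top_fraction")` and `attr(, "sided")`.
#' @export
percentile_threshold <- function(corrs, top_fraction = 0.05,
                                 sided = c("two", "negative"),
                                 scope = c("dataset", "per-source")) {
  sided <- match.arg(sided)
  scope <- match.arg(scope)
  stopifnot(top_fraction > 0, top_fraction < 1)
  rho <- corrs$rho
  if (sum(is.finite(rho)) < 20) {
    stop("need at least 20 finite correlations in scope")
  }
  cutoff_of <- function(r) {
    r <- r[is.finite(r)]
    k <- ceiling(top_fraction * length(r))
    if (length(r) < 1 / top_fraction) {
      warning("fewer correlations than 1/top_fraction; selection may be empty")
    }
    if (sided == "two") sort(abs(r), decreasing = TRUE)[k] else sort(r)[k]
  }
  if (scope == "dataset") {
    cut <- cutoff_of(rho)
    cuts <- cut
  } else {
    cuts <- vapply(split(rho, corrs$source), cutoff_of, numeric(1))
    cut <- cuts[as.character(corrs$source)]
  }
  if (sided == "two") {
    sel <- is.finite(rho) & abs(rho) >= cut
    corrs$selected_pos <- sel & rho > 0
    corrs$selected_neg <- sel & rho < 0
  } else {
    corrs$selected_pos <- FALSE
    corrs$selected_neg <- is.finite(rho) & rho <= cut
  }
  attr(corrs, "realized_cutoff") <- cuts
  attr(corrs, "top_fraction") <- top_fraction
  attr(corrs, "sided") <- sided
  attr(corrs, "scope") <- scope
  corrs
}
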