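#' Bray-Curtis dissimilarity between samples
#'
#' d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk), computed over the
#' columns (samples) of a compositional matrix. Bounded in \[0, 1\] for
#' non-negative profiles.
#'
#' @param m an [intensity_matrix()]/[abundance_matrix()] (normalized), or a
#'   plain non-negative numeric matrix with samples in columns.
#' @return a `dist` object labelled by sample id.
#' @export
bray_curtis <- function(m) {
  x <- if (inherits(m, "sample_matrix")) {
    if (!m$normalized) stop("matrix must be normalized; see normalize_tic()")
    m$values
  } else {
    stopifnot(is.matrix(m), is.numeric(m))
    m
  }
  if (any(x < 0)) stop("Bray-Curtis requires non-negative values")
  totals <- colSums(x)
  num <- stats::dist(t(x), method = "manhattan")
  den <- stats::as.dist(outer(totals, totals, "+"))
  if (any(den == 0)) {
    stop("sample pair(s) with all-zero combined profile: distance undefined")
  }
  out <- num / den
  attr(out, "Labels") <- colnames(x)
  attr(out, "method") <- "bray-curtis"
  out
}
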