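#' Principal coordinate analysis (metric multidimensional scaling)
#'
#' Gower double-centering of -d^2/2 followed by an eigendecomposition.
#' Axes with eigenvalues above a relative tolerance are retained, scaled as
#' eigenvector * sqrt(eigenvalue). Negative eigenvalues (from non-Euclidean
#' dissimilarities such as Bray-Curtis) are counted and excluded from the
#' variance-explained denominator; no Lingoes/Cailliez correction is
#' applied.
#'
#' @param d a `dist` object or symmetric dissimilarity matrix.
#' @param tol relative eigenvalue tolerance (default 1e-8 of the largest).
#' @return object of class `pcoa_ordination`: list with `coords` (samples x
#'   axes), `eigenvalues` (all, descending), `prop_explained` (per retained
#'   axis, relative to the sum of positive eigenvalues),
#'   `n_negative_eigenvalues`, and `labels`.
#' @export
pcoa <- function(d, tol = 1e-8) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 3) stop("too few samples for PCoA (need at least 3)")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lambda <- eg$values
  scale0 <- max(abs(lambda), .Machine$double.eps)
  keep <- lambda > tol * scale0
  n_neg <- sum(lambda < -tol * scale0)
  if (n_neg > 0) {
    warning(n_neg, " negative eigenvalue(s); excluded from prop_explained")
  }
  if (!any(keep)) {
    coords <- matrix(0, n, 1, dimnames = list(labels, "Axis1"))
    prop <- 0
  } else {
    coords <- eg$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(lambda[keep]), sum(keep))
    dimnames(coords) <- list(labels, paste0("Axis", seq_len(sum(keep))))
    prop <- lambda[keep] / sum(lambda[lambda > 0])
  }
  structure(list(coords = coords, eigenvalues = lambda,
                 prop_explained = prop, n_negative_eigenvalues = n_neg,
                 labels = labels),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("<pcoa_ordination> %d samples, %d retained axes, %d negative eigenvalue(s)\n",
              nrow(x$coords), ncol(x$coords), x$n_negative_eigenvalues))
  cat("prop explained (first axes):",
      paste(sprintf("%.1f%%", 100 * utils::head(x$prop_explained, 4)),
            collapse = ", "), "\n")
  invisible(x)
}

#' PCoA axes covering a target share of positive inertia
#'
#' Used to parameterize dbRDA: the predictor block is the leading axes of
#' the explanatory ordination that together explain at least `target` of its
#' positive inertia.
#'
#' @param ord a [pcoa()] result.
#' @param target cumulative proportion of positive inertia (default 0.9).
#' @return data.frame of axis scores (samples x axes).
#' @export
pcoa_predictors <- function(ord, target = 0.9) {
  stopifnot(inherits(ord, "pcoa_ordination"))
  k <- which(cumsum(ord$prop_explained) >= target)[1]
  if (is.na(k)) k <- ncol(ord$coords)
  as.data.frame(ord$coords[, seq_len(k), drop = FALSE])
}

#' Fit environmental vectors onto an ordination
#'
#' Regresses each variable on the first `n_axes` ordination scores; the
#' arrow is the unit-normalized coefficient vector, r2 the regression R^2,
#' and the p-value comes from permuting the variable across samples.
#'
#' @param ord a [pcoa()] result (or matrix of scores).
#' @param vars data.frame of per-sample numeric variables, rows aligned with
#'   the ordination samples.
#' @param n_axes number of leading axes to fit onto (default 2).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame: `variable`, one direction-cosine column per axis,
#'   `r2`, `p_value`, `zero_variance` flag.
#' @export
envfit_vectors <- function(ord, vars, n_axes = 2, n_perm = 999, seed = NULL) {
  scores <- if (inherits(ord, "pcoa_ordination")) ord$coords else as.matrix(ord)
  n_axes <- min(n_axes, ncol(scores))
  S <- scores[, seq_len(n_axes), drop = FALSE]
  stopifnot(nrow(vars) == nrow(S))
  Sc <- sweep(S, 2, colMeans(S))
  fit_one <- function(y) {
    yc <- y - mean(y)
    tss <- sum(yc^2)
    cf <- qr.coef(qr(Sc), yc)
    cf[is.na(cf)] <- 0
    r2 <- 1 - sum((yc - Sc %*% cf)^2) / tss
    list(coef = cf, r2 = r2)
  }
  with_seed(seed, {
    rows <- lapply(names(vars), function(v) {
      y <- as.numeric(vars[[v]])
      if (stats::var(y) == 0) {
        return(data.frame(variable = v, t(rep(0, n_axes)), r2 = 0,
                          p_value = 1, zero_variance = TRUE))
      }
      obs <- fit_one(y)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        if (fit_one(y[sample.int(length(y))])$r2 >= obs$r2 - 1e-12) {
          hits <- hits + 1L
        }
      }
      dir <- unname(obs$coef / sqrt(sum(obs$coef^2)))
      data.frame(variable = v, t(dir), r2 = obs$r2,
                 p_value = (1 + hits) / (1 + n_perm), zero_variance = FALSE)
    })
    out <- do.call(rbind, rows)
    names(out)[2:(1 + n_axes)] <- paste0("axis", seq_len(n_axes))
    rownames(out) <- NULL
    out
  })
}

#' Symmetric Procrustes superimposition with a PROTEST permutation test
#'
#' Both configurations are centered and scaled to unit sum of squares; the
#' optimal rotation comes from the SVD of the cross-product. The statistic
#' is m2 = 1 - (sum of singular values)^2, so protest_r = sqrt(1 - m2).
#' Significance is assessed by permuting the row order of the second
#' configuration.
#'
#' @param a,b [pcoa()] results (their retained axes are used) or score
#'   matrices with matching row labels.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list of class `procrustes_result`: `m2`, `protest_r`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
procrustes_protest <- function(a, b, n_perm = 999, seed = NULL) {
  Xa <- if (inherits(a, "pcoa_ordination")) a$coords else as.matrix(a)
  Xb <- if (inherits(b, "pcoa_ordination")) b$coords else as.matrix(b)
  la <- rownames(Xa); lb <- rownames(Xb)
  if (is.null(la) || is.null(lb)) stop("both configurations need row labels")
  if (!setequal(la, lb)) {
    stop("sample sets differ: only in first: ",
         paste(setdiff(la, lb), collapse = ", "), "; only in second: ",
         paste(setdiff(lb, la), collapse = ", "))
  }
  Xb <- Xb[match(la, lb), , drop = FALSE]
  k <- max(ncol(Xa), ncol(Xb))
  pad <- function(X) {
    if (ncol(X) < k) X <- cbind(X, matrix(0, nrow(X), k - ncol(X)))
    X
  }
  unitize <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    ss <- sum(X^2)
    if (ss <= 0) stop("degenerate configuration (zero spread)")
    X / sqrt(ss)
  }
  X <- unitize(pad(Xa))
  Y <- unitize(pad(Xb))
  stat <- function(Yp) sum(svd(crossprod(X, Yp))$d)  # in [0, 1]
  r_obs <- stat(Y)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      Yp <- unitize(Y[sample.int(nrow(Y)), , drop = FALSE])
      if (stat(Yp) >= r_obs - 1e-12) hits <- hits + 1L
    }
    structure(list(m2 = 1 - r_obs^2, protest_r = r_obs,
                   p_value = (1 + hits) / (1 + n_perm),
                   n_permutations = n_perm, seed = seed),
              class = "procrustes_result")
  })
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> m2 = %.4f, protest r = %.4f, p = %.4g (%d permutations)\n",
              x$m2, x$protest_r, x$p_value, x$n_permutations))
  invisible(x)
}
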