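#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' McArdle-Anderson formulation on an arbitrary dissimilarity matrix: with
#' G the Gower-centered matrix of -d^2/2 and H the hat matrix of the model,
#' pseudo-F = \[tr(HGH)/q\] / \[tr((I-H)G(I-H))/(n-q-1)\] and
#' R2 = tr(HGH)/tr(G). Terms are assessed sequentially (in formula order)
#' against the full-model residual. The p-value compares the observed
#' pseudo-F to its distribution under random permutation of sample labels,
#' with the add-one convention (1 + hits) / (1 + n_perm).
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param design data.frame of predictors, rows aligned with the samples of
#'   `d` (factors or numeric).
#' @param formula right-hand-side model formula over `design` columns;
#'   default uses all columns additively.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed recorded in the result.
#' @param strata optional factor restricting permutations to within-stratum
#'   shuffles (repeated-measures designs); default unrestricted.
#' @return object of class `permanova_result`: `table` (per-term df, SS,
#'   R2, pseudo-F, p), overall `pseudo_F`, `R2`, `p_value`, plus
#'   `n_permutations` and `seed`.
#' @export
permanova <- function(d, design, formula = NULL, n_perm = 999, seed = NULL,
                      strata = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  design <- as.data.frame(design)
  stopifnot(nrow(design) == n)
  if (is.null(formula)) {
    formula <- stats::reformulate(names(design))
  }
  X <- stats::model.matrix(formula, data = design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient model matrix; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(formula, data = design), "term.labels")
  if (!length(term_labels)) stop("model has no terms")

  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  trG <- sum(diag(G))
  if (trG <= 1e-12) {
    warning("degenerate distance matrix (no variation); p = 1")
    tab <- data.frame(term = c(term_labels, "Residual", "Total"), df = NA,
                      SS = 0, R2 = NA, pseudo_F = NA, p_value = NA)
    return(structure(list(table = tab, pseudo_F = 0, R2 = 0, p_value = 1,
                          n_permutations = n_perm, seed = seed),
                     class = "permanova_result"))
  }

  # cumulative hat matrices, intercept first then one per added term
  hats <- vector("list", length(term_labels))
  ranks <- integer(length(term_labels))
  for (k in seq_along(term_labels)) {
    Xk <- X[, assign <= k, drop = FALSE]
    qk <- qr(Xk)
    Q <- qr.Q(qk)[, seq_len(qk$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
    ranks[k] <- qk$rank
  }
  df_term <- diff(c(1L, ranks))
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("no residual degrees of freedom")

  term_ss <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    diff(c(0, tr))  # intercept contributes 0 on a Gower-centered G
  }
  ss_obs <- term_ss(G)
  ss_res <- max(trG - sum(ss_obs), 0)
  f_obs <- (ss_obs / df_term) / (ss_res / df_res)
  df_model <- sum(df_term)
  f_model <- (sum(ss_obs) / df_model) / (ss_res / df_res)

  perm_index <- function() {
    if (is.null(strata)) return(sample.int(n))
    idx <- seq_len(n)
    for (lev in unique(strata)) {
      w <- which(strata == lev)
      idx[w] <- w[sample.int(length(w))]
    }
    idx
  }

  with_seed(seed, {
    hits <- rep(0L, length(term_labels))
    hits_model <- 0L
    for (b in seq_len(n_perm)) {
      p <- perm_index()
      ss_b <- term_ss(G[p, p])
      res_b <- max(trG - sum(ss_b), 0)
      f_b <- (ss_b / df_term) / (res_b / df_res)
      hits <- hits + (f_b >= f_obs - 1e-12)
      fm_b <- (sum(ss_b) / df_model) / (res_b / df_res)
      if (fm_b >= f_model - 1e-12) hits_model <- hits_model + 1L
    }
    tab <- data.frame(
      term = c(term_labels, "Residual", "Total"),
      df = c(df_term, df_res, n - 1L),
      SS = c(ss_obs, ss_res, trG),
      R2 = c(ss_obs, ss_res, trG) / trG,
      pseudo_F = c(f_obs, NA, NA),
      p_value = c((1 + hits) / (1 + n_perm), NA, NA)
    )
    structure(list(table = tab, pseudo_F = f_model,
                   R2 = sum(ss_obs) / trG,
                   p_value = (1 + hits_model) / (1 + n_perm),
                   n_permutations = n_perm, seed = seed),
              class = "permanova_result")
  })
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> overall pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Distance-based redundancy analysis (dbRDA)
#'
#' Quantifies the fraction of a dissimilarity matrix explained by a block of
#' numeric predictors: the same engine as [permanova()] with all predictors
#' entering as one constrained block, so R2 = tr(HGH)/tr(G) is the
#' constrained inertia fraction.
#'
#' @param response_d `dist` or dissimilarity matrix.
#' @param predictors data.frame of numeric predictors (e.g. the explanatory
#'   ordination's axes from [pcoa_predictors()]).
#' @param n_perm,seed,strata see [permanova()].
#' @return a `permanova_result` with a single constrained term.
#' @export
dbrda <- function(response_d, predictors, n_perm = 999, seed = NULL,
                  strata = NULL) {
  predictors <- as.data.frame(predictors)
  if (!all(vapply(predictors, is.numeric, logical(1)))) {
    stop("dbRDA predictors must all be numeric")
  }
  block <- as.matrix(predictors)
  df <- data.frame(row.names = seq_len(nrow(block)))
  df$constrained <- block  # matrix column: one model term for the block
  permanova(response_d, df, formula = ~constrained, n_perm = n_perm,
            seed = seed, strata = strata)
}
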