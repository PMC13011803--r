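#' Exact multinomial goodness-of-fit test
#'
#' Tests observed category counts against a fixed probability vector.
#' The p-value sums the probabilities of all outcome vectors whose
#' multinomial probability does not exceed that of the observed vector
#' (the small-probability ordering). Exact enumeration is used up to
#' `exact_limit` total counts; above that a seeded Monte-Carlo estimate
#' over `n_mc` draws is returned (with the add-one convention) and flagged
#' in `method`.
#'
#' @param observed non-negative integer counts.
#' @param probs null category probabilities, summing to 1 (within 1e-9).
#' @param exact_limit largest n for exhaustive enumeration (default 60).
#' @param n_mc Monte-Carlo draws beyond `exact_limit` (default 1e5).
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return list of class `multinomial_test`: `p_value`, `method`
#'   (`"exact"` or `"monte_carlo"`), `n`, `observed`, `probs`.
#' @examples
#' exact_multinomial_test(c(3, 0, 0), rep(1 / 3, 3))$p_value  # 3/27
#' @export
exact_multinomial_test <- function(observed, probs, exact_limit = 60,
                                   n_mc = 1e5, seed = NULL) {
  observed <- as.integer(round(observed))
  stopifnot(all(observed >= 0), length(observed) == length(probs),
            length(observed) >= 2)
  if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1 (within 1e-9)")
  n <- sum(observed)
  k <- length(observed)
  p_obs <- stats::dmultinom(observed, prob = probs)
  tol <- p_obs * (1 + 1e-7)
  if (n <= exact_limit) {
    comps <- .compositions(n, k)
    lp <- lgamma(n + 1) - rowSums(lgamma(comps + 1)) +
      as.numeric(comps %*% ifelse(probs > 0, log(probs), 0))
    # outcomes using a zero-probability category are impossible
    imposs <- rowSums(comps[, probs == 0, drop = FALSE]) > 0
    pr <- exp(lp)
    pr[imposs] <- 0
    p <- sum(pr[pr <= tol])
    method <- "exact"
  } else {
    p <- with_seed(seed, {
      draws <- stats::rmultinom(n_mc, n, probs)
      lp <- lgamma(n + 1) - colSums(lgamma(draws + 1)) +
        colSums(draws * ifelse(probs > 0, log(probs), 0))
      (1 + sum(exp(lp) <= tol)) / (1 + n_mc)
    })
    method <- "monte_carlo"
  }
  structure(list(p_value = min(p, 1), method = method, n = n,
                 observed = observed, probs = probs),
            class = "multinomial_test")
}

# all k-part compositions of n (rows sum to n)
.compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- lapply(0:n, function(i) cbind(i, .compositions(n - i, k - 1)))
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

#' Exact binomial test
#'
#' One-sided tail sums, or two-sided by the small-probability ordering (sum
#' of all outcome probabilities not exceeding that of the observed count).
#'
#' @param k observed successes (0 <= k <= n).
#' @param n number of trials.
#' @param p0 null success probability.
#' @param side `"two"`, `"greater"` or `"less"`.
#' @return the p-value.
#' @examples
#' exact_binomial_test(0, 5, 0.5, "two")  # 0.0625
#' @export
exact_binomial_test <- function(k, n, p0, side = c("two", "greater", "less")) {
  side <- match.arg(side)
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  d <- stats::dbinom(0:n, n, p0)
  p <- switch(side,
    greater = sum(d[(k + 1):(n + 1)]),
    less = sum(d[1:(k + 1)]),
    two = sum(d[d <= d[k + 1] * (1 + 1e-7)])
  )
  min(p, 1)
}

#' Compound-class enrichment of time-correlated formulae
#'
#' Given a thresholded formula-by-time correlation table, tests per
#' (source, class) whether the numbers of selected positive and negative
#' correlations deviate from the equal-split null. Under the default
#' three-category model the null is multinomial with probabilities
#' (f/2, f/2, 1 - f) for (selected-positive, selected-negative,
#' unselected), where f is the selection fraction; the two-category
#' alternative conditions on selection and tests pos vs neg at 1/2 each.
#' Classes with a significant multinomial deviation get post hoc one-sided
#' binomial tests of each direction against Binomial(n_class, f/2), which
#' set the verdict (preferentially produced / consumed / both). No
#' multiplicity correction is applied by default; `p_adjust = "BH"`
#' switches Benjamini-Hochberg adjustment of the multinomial p-values on.
#'
#' @param corrs output of [percentile_threshold()] on a [correlate_time()]
#'   table (two-sided).
#' @param annotations annotation table covering the formulae.
#' @param alpha verdict significance level (default 0.05).
#' @param model `"three"` (default) or `"two"` category null.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param seed RNG seed for Monte-Carlo multinomial calls.
#' @param ... passed to [exact_multinomial_test()].
#' @return data.frame of class `class_enrichment`: `source`,
#'   `compound_class`, `n_class`, `k_pos`, `k_neg`, `p_multinomial`,
#'   `p_binomial_pos`, `p_binomial_neg`, `verdict`.
#' @export
class_enrichment <- function(corrs, annotations, alpha = 0.05,
                             model = c("three", "two"),
                             p_adjust = c("none", "BH"), seed = NULL, ...) {
  model <- match.arg(model)
  p_adjust <- match.arg(p_adjust)
  f <- attr(corrs, "top_fraction")
  if (is.null(f)) stop("`corrs` must come from percentile_threshold()")
  cls <- annotations$compound_class[match(corrs$formula_id,
                                          annotations$formula_id)]
  if (anyNA(cls)) stop("annotations missing for some formula ids")
  cells <- split(seq_len(nrow(corrs)),
                 list(source = corrs$source, class = cls), drop = TRUE)
  rows <- lapply(seq_along(cells), function(i) {
    idx <- cells[[i]]
    key <- strsplit(names(cells)[i], ".", fixed = TRUE)[[1]]
    n <- length(idx)
    k_pos <- sum(corrs$selected_pos[idx])
    k_neg <- sum(corrs$selected_neg[idx])
    if (model == "three") {
      mt <- exact_multinomial_test(c(k_pos, k_neg, n - k_pos - k_neg),
                                   c(f / 2, f / 2, 1 - f),
                                   seed = derive_seed(seed, i), ...)
    } else {
      ksel <- k_pos + k_neg
      mt <- if (ksel == 0) list(p_value = 1) else
        exact_multinomial_test(c(k_pos, k_neg), c(0.5, 0.5),
                               seed = derive_seed(seed, i), ...)
    }
    data.frame(source = key[1], compound_class = paste(key[-1], collapse = "."),
               n_class = n, k_pos = k_pos, k_neg = k_neg,
               p_multinomial = mt$p_value,
               p_binomial_pos = exact_binomial_test(k_pos, n, f / 2, "greater"),
               p_binomial_neg = exact_binomial_test(k_neg, n, f / 2, "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_used <- if (p_adjust == "BH") stats::p.adjust(out$p_multinomial, "BH") else
    out$p_multinomial
  pos_sig <- p_used < alpha & out$p_binomial_pos < alpha
  neg_sig <- p_used < alpha & out$p_binomial_neg < alpha
  out$verdict <- ifelse(pos_sig & neg_sig, "both",
                 ifelse(neg_sig, "preferentially consumed",
                 ifelse(pos_sig, "preferentially produced", "none")))
  out <- out[order(out$source, out$compound_class), ]
  rownames(out) <- NULL
  class(out) <- c("class_enrichment", class(out))
  out
}
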