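# Rank-based tests implemented from first principles. These primitives are
# the package's own: base R equivalents are used only as independent
# cross-checks in the test suite.

midrank <- function(x) rank(x, ties.method = "average")

#' Paired Wilcoxon signed-rank test with exact enumeration
#'
#' Tests whether paired differences `x - y` are shifted away from zero.
#' Zero differences are dropped (the classical Wilcoxon convention, not
#' Pratt's). Absolute differences receive midranks; the statistic is
#' `W+`, the sum of ranks of positive differences. The p-value is exact —
#' computed from the full distribution of `W+` over all `2^n` sign
#' assignments — whenever `n <= 25` and there are no ties among the
#' absolute differences; otherwise a normal approximation with tie
#' correction and a 0.5 continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"greater"` (x tends to exceed y), `"less"`, or
#'   `"two.sided"`.
#' @param exact_max largest `n` for which the exact distribution is
#'   enumerated (default 25).
#' @return An `engraft_test` list: `method`, `statistic` (W+), `n_pairs`
#'   (non-zero differences), `p`, `p_adjusted` (`NA` until a family
#'   adjustment is applied), `alternative`, `exact` flag, `degenerate` flag.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("greater", "less", "two.sided"),
                                 exact_max = 25) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (!length(x)) stop("empty input", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  res <- list(method = "wilcoxon_signed_rank", statistic = 0, n_pairs = n,
              p = 1, p_adjusted = NA_real_, alternative = alternative,
              exact = TRUE, degenerate = FALSE)
  class(res) <- "engraft_test"
  if (n == 0) {
    res$degenerate <- TRUE
    return(res)
  }
  r <- midrank(abs(d))
  w_pos <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  use_exact <- !ties && n <= exact_max
  if (use_exact) {
    # distribution of W+ over sign flips: convolution over ranks 1..n
    probs <- signrank_distribution(n)
    w <- round(w_pos)
    p_ge <- sum(probs[seq.int(w + 1L, n * (n + 1) / 2 + 1L)])
    p_le <- sum(probs[seq.int(1L, w + 1L)])
    res$p <- switch(alternative,
                    greater = p_ge,
                    less = p_le,
                    two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    z_ge <- (w_pos - mu - 0.5) / sigma
    z_le <- (w_pos - mu + 0.5) / sigma
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    res$p <- switch(alternative,
                    greater = p_ge,
                    less = p_le,
                    two.sided = min(1, 2 * min(p_ge, p_le)))
    res$exact <- FALSE
  }
  res$statistic <- w_pos
  res
}

# Exact null pmf of W+ for n untied pairs: probs[w + 1] = P(W+ = w),
# w in 0..n(n+1)/2. Dynamic programming over ranks.
signrank_distribution <- function(n) {
  counts <- 1  # number of sign assignments reaching each sum, starting at 0
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts)
    counts <- c(counts, rep(0, k)) + shifted
  }
  counts / 2^n
}

#' @export
print.engraft_test <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g, n=%d, %s p=%.4g%s%s\n",
              x$method, x$statistic, x$n_pairs, x$alternative, x$p,
              if (!is.na(x$p_adjusted)) sprintf(", BH-adjusted p=%.4g", x$p_adjusted) else "",
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: sort the m p-values increasingly, compute
#' `p_(i) * m / i`, and enforce monotonicity from the largest rank down.
#'
#' @param p numeric vector of p-values.
#' @return Vector of adjusted p-values in the original order, capped at 1.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  ranks <- m:1
  adj <- pmin(1, cummin(p[ord] * m / ranks))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic on midranks with the tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; p-value from the chi-squared
#' distribution with `k - 1` degrees of freedom. The chi-squared
#' approximation is used at all sample sizes (a documented limitation at
#' very small `n`; the test suite checks it against a permutation oracle).
#'
#' @param groups list of numeric vectors, one per group.
#' @return An `engraft_test` list with `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  n_j <- lengths(groups)
  if (any(n_j == 0)) stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (N < 3) stop("need >= 3 observations in total", call. = FALSE)
  res <- list(method = "kruskal_wallis", statistic = 0, n_pairs = N,
              df = k - 1, p = 1, p_adjusted = NA_real_,
              alternative = "two.sided", exact = FALSE, degenerate = FALSE)
  class(res) <- "engraft_test"
  if (length(unique(x)) == 1) {
    res$degenerate <- TRUE
    return(res)
  }
  r <- midrank(x)
  g <- rep(seq_len(k), n_j)
  rbar <- tapply(r, g, mean)
  h <- 12 / (N * (N + 1)) * sum(n_j * (rbar - (N + 1) / 2)^2)
  tie_tab <- table(x)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  h <- h / corr
  res$statistic <- h
  res$p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  res
}
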