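#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of the squared distance matrix,
#' `B = -1/2 J D^2 J` with `J = I - 11'/n`, followed by an
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues — which arise
#' when the distances are not Euclidean-embeddable, as with UniFrac — are
#' excluded from the axes and reported as a diagnostic mass; no
#' Lingoes/Cailliez correction is applied.
#'
#' @param d a square symmetric distance matrix (see [unifrac()]).
#' @param n_axes number of axes requested (default 2). If fewer positive
#'   eigenvalues exist, fewer axes are returned with a warning.
#' @return An `ordination` list: `coordinates` (samples x axes),
#'   `eigenvalues` (all, decreasing), `proportion_explained` (over positive
#'   eigenvalues, per returned axis), `negative_eigenvalue_mass`
#'   (sum |negative| / sum |all|).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- validate_dist_matrix(as.matrix(d))
  n <- nrow(d)
  if (n_axes >= n) stop("n_axes must be smaller than the number of samples",
                        call. = FALSE)
  d2 <- d^2
  centered <- sweep(d2, 1, rowMeans(d2))
  centered <- sweep(centered, 2, colMeans(centered))
  b <- -centered / 2
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-9
  pos <- which(vals > tol)
  if (length(pos) < n_axes) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            length(pos), " axes")
    n_axes <- length(pos)
  }
  axes <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, axes, drop = FALSE] %*%
    diag(sqrt(vals[axes]), n_axes)
  dimnames(coords) <- list(rownames(d), paste0("PCo", seq_len(n_axes)))
  structure(list(
    coordinates = coords,
    eigenvalues = vals,
    proportion_explained = vals[axes] / sum(vals[pos]),
    negative_eigenvalue_mass = sum(abs(vals[vals < -tol])) / sum(abs(vals))
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  pe <- x$proportion_explained
  cat(sprintf("PCoA: %d samples, %d axes (%s); negative-eigenvalue mass %.3f\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * pe), collapse = ", "),
              x$negative_eigenvalue_mass))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based comparison of between-group versus within-group distances:
#' all `n(n-1)/2` off-diagonal distances receive midranks and
#' `R = (mean_between - mean_within) / (M/2)` with `M = n(n-1)/2`.
#' Significance is assessed by label permutation: exhaustively, when the
#' number of distinct label arrangements is at most `exact_max`, or by
#' seeded Monte Carlo otherwise, with
#' `p = (1 + #permuted R >= observed R) / (1 + n_permutations)`.
#'
#' @param d square symmetric distance matrix.
#' @param labels group label per sample (length `nrow(d)`), each group with
#'   at least 2 members.
#' @param n_permutations Monte-Carlo permutations (default 999).
#' @param seed RNG seed for the Monte-Carlo draw.
#' @param method `"auto"` (exhaustive when feasible), `"exact"`, or
#'   `"permutation"`.
#' @param exact_max largest number of distinct arrangements enumerated
#'   exhaustively under `"auto"` (default 10000).
#' @return An `anosim_result` list: `R`, `p`, `n_permutations` (actual
#'   arrangements evaluated), `exact`, `seed`.
#' @export
anosim <- function(d, labels, n_permutations = 999, seed = 1L,
                   method = c("auto", "exact", "permutation"),
                   exact_max = 10000) {
  method <- match.arg(method)
  d <- validate_dist_matrix(as.matrix(d))
  labels <- as.character(labels)
  n <- nrow(d)
  if (length(labels) != n) stop("labels length must match matrix", call. = FALSE)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("group(s) of size 1: ", paste(names(sizes)[sizes < 2], collapse = ", "),
         call. = FALSE)
  }
  lower <- lower.tri(d)
  r <- midrank(d[lower])
  m_pairs <- n * (n - 1) / 2
  same <- outer(labels, labels, `==`)[lower]
  r_stat <- function(same_vec) {
    (mean(r[!same_vec]) - mean(r[same_vec])) / (m_pairs / 2)
  }
  observed <- r_stat(same)

  n_arrangements <- multinomial_count(as.integer(sizes))
  use_exact <- method == "exact" ||
    (method == "auto" && n_arrangements <= exact_max)
  if (use_exact) {
    perms <- label_arrangements(sort(rep(seq_along(sizes), sizes)))
    stats <- vapply(perms, function(lab) {
      r_stat(outer(lab, lab, `==`)[lower])
    }, numeric(1))
    p <- sum(stats >= observed - 1e-12) / length(stats)
    out <- list(R = observed, p = p, n_permutations = length(stats),
                exact = TRUE, seed = NA_integer_)
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
      lab <- sample(labels)
      r_stat(outer(lab, lab, `==`)[lower])
    }, numeric(1)))
    p <- (1 + sum(stats >= observed - 1e-12)) / (1 + n_permutations)
    out <- list(R = observed, p = p, n_permutations = n_permutations,
                exact = FALSE, seed = seed)
  }
  class(out) <- "anosim_result"
  out
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R=%.4f, p=%.4g (%s, %d arrangements)\n",
              x$R, x$p, if (x$exact) "exhaustive" else "Monte Carlo",
              x$n_permutations))
  invisible(x)
}

multinomial_count <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# All distinct assignments of group labels to positions, as a list of
# integer vectors. Recursive: choose the positions of each group in turn.
label_arrangements <- function(labels) {
  n <- length(labels)
  groups <- unique(labels)
  recurse <- function(positions, remaining_groups) {
    g <- remaining_groups[1]
    k <- sum(labels == g)
    if (length(remaining_groups) == 1) {
      lab <- integer(n)
      lab[positions] <- g
      return(list(lab))
    }
    out <- list()
    for (pick in utils::combn(seq_along(positions), k, simplify = FALSE)) {
      rest <- recurse(positions[-pick], remaining_groups[-1])
      for (lab in rest) {
        lab[positions[pick]] <- g
        out[[length(out) + 1]] <- lab
      }
    }
    out
  }
  recurse(seq_len(n), groups)
}
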