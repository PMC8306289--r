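# UniFrac computed directly from the branch partition of a rooted tree.
# For every edge we accumulate, by a single postorder pass, the summed
# relative abundance of the leaves below it in each sample; unweighted
# UniFrac compares branch presence (unique vs union branch length),
# weighted UniFrac compares abundance mass flowing through each branch.

#' Pairwise UniFrac distances for all samples
#'
#' @param table a [count_table()] (samples x ASVs).
#' @param tree rooted `ape::phylo` tree whose tips cover every ASV with a
#'   nonzero count (unrooted trees are midpoint-rooted, see
#'   [read_newick()]).
#' @param metric `"unweighted"` or `"weighted"`.
#' @param normalized for the weighted metric, divide by the
#'   abundance-weighted root-to-leaf depth sum so values fall in `[0, 1]`.
#'   Default `FALSE` (the original raw weighted metric).
#' @return A `dist_matrix`: symmetric numeric matrix with zero diagonal and
#'   sample ids as dimnames.
#' @export
unifrac <- function(table, tree, metric = c("unweighted", "weighted"),
                    normalized = FALSE) {
  metric <- match.arg(metric)
  prep <- unifrac_prepare(table, tree)
  n <- nrow(prep$edge_mass)
  len <- prep$edge_len
  if (metric == "unweighted") {
    ind <- prep$edge_mass > 0
    weighted_ind <- ind * rep(len, each = n)
    num <- as.matrix(stats::dist(weighted_ind, method = "manhattan"))
    shared <- weighted_ind %*% t(ind)        # sum len over branches in both
    totals <- rowSums(weighted_ind)
    denom <- outer(totals, totals, `+`) - shared
    d <- num / denom
    diag(d) <- 0
  } else {
    mass_len <- prep$edge_mass * rep(len, each = n)
    d <- as.matrix(stats::dist(mass_len, method = "manhattan"))
    if (normalized) {
      q <- rowSums(prep$prop * rep(prep$tip_depth, each = n))
      d <- d / outer(q, q, `+`)
      diag(d) <- 0
    }
  }
  dimnames(d) <- list(prep$sample_ids, prep$sample_ids)
  structure(d, metric = metric, class = c("dist_matrix", "matrix", "array"))
}

#' Unweighted UniFrac distance between two samples
#'
#' Unique branch length over union branch length, where a branch counts for
#' a sample iff any leaf below it is present in that sample.
#'
#' @inheritParams unifrac
#' @param pair character vector of two sample ids.
#' @return Distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree, pair) {
  d <- unifrac(subset_samples(table, pair), tree, metric = "unweighted")
  d[pair[1], pair[2]]
}

#' Weighted UniFrac distance between two samples
#'
#' Branch-length-weighted L1 difference of the abundance mass below each
#' branch; optionally normalized to `[0, 1]`.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized see [unifrac()].
#' @return Non-negative distance.
#' @export
weighted_unifrac <- function(table, tree, pair, normalized = FALSE) {
  d <- unifrac(subset_samples(table, pair), tree, metric = "weighted",
               normalized = normalized)
  d[pair[1], pair[2]]
}

subset_samples <- function(table, ids) {
  check_samples_present(table, ids)
  m <- unclass(as.matrix(table))[ids, , drop = FALSE]
  count_table(m)
}

# Shared precomputation: per-edge descendant abundance of every sample.
unifrac_prepare <- function(table, tree) {
  tree <- validate_tree(tree)
  prop_full <- relative_abundance(table)
  present_asvs <- colnames(prop_full)[colSums(prop_full) > 0]
  missing <- setdiff(present_asvs, tree$tip.label)
  if (length(missing)) {
    stop("ASV(s) present in samples but absent from tree: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n <- nrow(prop_full)
  # samples x tips proportion matrix (tips absent from the table get 0)
  prop <- matrix(0, n, ntip, dimnames = list(rownames(prop_full), tree$tip.label))
  common <- intersect(colnames(prop_full), tree$tip.label)
  prop[, common] <- prop_full[, common]

  po <- stats::reorder(tree, "postorder")
  node_mass <- matrix(0, ntip + nnode, n)
  node_mass[seq_len(ntip), ] <- t(prop)
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]
    parent <- po$edge[e, 1]
    node_mass[parent, ] <- node_mass[parent, ] + node_mass[child, ]
  }
  list(
    sample_ids = rownames(prop_full),
    prop = prop,
    edge_mass = t(node_mass[po$edge[, 2], , drop = FALSE]),  # samples x edges
    edge_len = po$edge.length,
    tip_depth = ape::node.depth.edgelength(tree)[seq_len(ntip)]
  )
}

#' Read/write a square distance matrix as TSV
#' @param d a `dist_matrix` (square symmetric matrix with dimnames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  validate_dist_matrix(m)
}

validate_dist_matrix <- function(m) {
  if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop("distance matrix must be square with matching sample ids", call. = FALSE)
  }
  if (any(m < 0)) stop("negative distance", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix not symmetric", call. = FALSE)
  if (any(abs(diag(m)) > 1e-12)) stop("nonzero diagonal", call. = FALSE)
  structure((m + t(m)) / 2, class = c("dist_matrix", "matrix", "array"))
}
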