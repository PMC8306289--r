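# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Exact one-sided ("greater") signed-rank p by enumerating all 2^n sign
# assignments of the non-zero differences, with midranks of |d|.
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(w_all >= w_obs - 1e-9)
}

# Per-branch brute-force UniFrac: for every edge, find its descendant
# leaves by walking the edge table, then apply the definitions directly.
oracle_unifrac <- function(tree, counts_a, counts_b, weighted = FALSE,
                           normalized = FALSE) {
  tips <- tree$tip.label
  ntip <- length(tips)
  desc_leaves <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_leaves))
  }
  pa <- counts_a / sum(counts_a)
  pb <- counts_b / sum(counts_b)
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    len <- tree$edge.length[e]
    below <- desc_leaves(tree$edge[e, 2])
    labs <- tips[below]
    if (weighted) {
      qa <- sum(pa[labs])
      qb <- sum(pb[labs])
      num <- num + len * abs(qa - qb)
    } else {
      ia <- any(pa[labs] > 0)
      ib <- any(pb[labs] > 0)
      num <- num + len * abs(ia - ib)
      den <- den + len * (ia || ib)
    }
  }
  if (weighted) {
    if (!normalized) return(num)
    depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
    names(depth) <- tips
    return(num / sum(depth * (pa[tips] + pb[tips])))
  }
  num / den
}

# ANOSIM R straight from its definition (no shared code with anosim()).
oracle_anosim_R <- function(d, labels) {
  lower <- lower.tri(d)
  r <- rank(d[lower])
  same <- outer(labels, labels, `==`)[lower]
  m <- sum(lower)
  (mean(r[!same]) - mean(r[same])) / (m / 2)
}

# Exhaustive ANOSIM p over all orderings of the label vector (duplicate
# arrangements appear equally often, leaving the tail probability
# unchanged).
oracle_anosim_exact_p <- function(d, labels) {
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- oracle_anosim_R(d, labels)
  stats <- vapply(all_perms(labels), function(lab) oracle_anosim_R(d, lab),
                  numeric(1))
  mean(stats >= obs - 1e-12)
}

# Random rooted tree + paired count fixture for UniFrac sweeps.
random_unifrac_case <- function(n_tips, seed) {
  tree <- simulate_tree(n_tips, seed = seed)
  with_seed <- function(s, expr) {  # local, avoids reaching into internals
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  with_seed(seed + 1000, {
    counts <- matrix(rpois(2 * n_tips, lambda = 3), nrow = 2,
                     dimnames = list(c("S1", "S2"), tree$tip.label))
    # guarantee both samples non-empty
    counts[1, 1] <- counts[1, 1] + 1
    counts[2, n_tips] <- counts[2, n_tips] + 1
    list(tree = tree, counts = counts)
  })
}

# Small complete simulated experiment reused across tests.
small_sim <- function(seed = 42, ...) {
  simulate_experiment(sim_config(n_asv_pool = 80, n_donor = 30, n_mouse = 25,
                                 read_depth = 2000, seed = seed, ...))
}
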