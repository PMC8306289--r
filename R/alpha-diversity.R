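#' Inverse Simpson diversity of one composition
#'
#' `1 / sum(p_i^2)`: the effective number of equally abundant taxa. Counts
#' are accepted and normalized internally, so the index is scale invariant.
#'
#' @param p non-negative numeric vector of proportions or counts, not all
#'   zero.
#' @return Inverse Simpson index, a real >= 1.
#' @export
inverse_simpson <- function(p) {
  if (any(p < 0) || anyNA(p)) stop("proportions must be non-negative", call. = FALSE)
  tot <- sum(p)
  if (tot <= 0) stop("all-zero composition", call. = FALSE)
  p <- p / tot
  1 / sum(p^2)
}

#' Observed richness of a count vector
#'
#' @param counts non-negative numeric vector of read counts.
#' @param min_count detection threshold (default 1).
#' @return Number of taxa with `count >= min_count`.
#' @export
richness <- function(counts, min_count = 1) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  sum(counts >= min_count)
}

#' Per-sample alpha diversity table
#'
#' Computes observed richness and inverse Simpson for every sample. No
#' rarefaction is applied by default; with `rarefy_depth`, each sample is
#' subsampled without replacement to that depth first (seeded), and samples
#' below the depth are dropped with a warning.
#'
#' @param table a [count_table()].
#' @param min_count detection threshold for richness.
#' @param rarefy_depth optional depth for seeded rarefaction.
#' @param seed RNG seed used when rarefying.
#' @return data.frame: `sample_id`, `richness`, `inverse_simpson`,
#'   `rarefied`, `depth_used`.
#' @export
alpha_diversity <- function(table, min_count = 1, rarefy_depth = NULL,
                            seed = 1L) {
  m <- unclass(as.matrix(table))
  storage.mode(m) <- "double"
  rarefied <- !is.null(rarefy_depth)
  if (rarefied) {
    keep <- rowSums(m) >= rarefy_depth
    if (!all(keep)) {
      warning("dropping ", sum(!keep), " sample(s) below rarefaction depth")
      m <- m[keep, , drop = FALSE]
    }
    m <- with_seed(seed, t(apply(m, 1, rarefy_vector, depth = rarefy_depth)))
  }
  data.frame(
    sample_id = rownames(m),
    richness = apply(m, 1, richness, min_count = min_count),
    inverse_simpson = apply(m, 1, inverse_simpson),
    rarefied = rarefied,
    depth_used = if (rarefied) rarefy_depth else NA_integer_,
    row.names = NULL
  )
}

rarefy_vector <- function(counts, depth) {
  picked <- sample(rep.int(seq_along(counts), counts), depth)
  tabulate(picked, nbins = length(counts))
}

#' Kruskal-Wallis comparison of alpha diversity across groups
#'
#' One test per timepoint (recipients only), comparing a diversity measure
#' across the experimental groups, mirroring per-timepoint box-plot panels.
#'
#' @param diversity output of [alpha_diversity()].
#' @param metadata validated metadata (see [read_metadata()]).
#' @param measure `"inverse_simpson"` or `"richness"`.
#' @return data.frame with one row per timepoint: `timepoint`, `n`,
#'   `statistic`, `df`, `p`.
#' @export
diversity_group_tests <- function(diversity, metadata,
                                  measure = c("inverse_simpson", "richness")) {
  measure <- match.arg(measure)
  md <- metadata[metadata$role == "recipient", ]
  merged <- merge(diversity, md, by = "sample_id")
  tps <- intersect(TIMEPOINT_LEVELS, unique(merged$timepoint))
  rows <- lapply(tps, function(tp) {
    sub <- merged[merged$timepoint == tp, ]
    groups <- split(sub[[measure]], sub$group)
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2) return(NULL)
    kw <- kruskal_wallis(groups)
    data.frame(timepoint = tp, n = nrow(sub), statistic = kw$statistic,
               df = kw$df, p = kw$p)
  })
  do.call(rbind, rows)
}
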