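#' @keywords internal
RANK_LEVELS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read an ASV taxonomy map from TSV
#'
#' Expects columns `asv_id` plus any prefix of the ranks kingdom, phylum,
#' class, order, family, genus. Missing ranks are encoded as empty strings;
#' a present rank below a missing one violates the lineage-prefix contract
#' and is an error.
#'
#' @param path TSV path.
#' @return data.frame with `asv_id` and rank columns (character, `""` for
#'   missing ranks).
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  validate_taxonomy(tax)
}

#' Write a taxonomy map to TSV
#' @param taxonomy taxonomy data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_taxonomy <- function(tax) {
  if (!"asv_id" %in% names(tax)) stop("taxonomy lacks asv_id column", call. = FALSE)
  ranks <- intersect(RANK_LEVELS, names(tax))
  if (!length(ranks)) stop("taxonomy has no recognised rank columns", call. = FALSE)
  if (anyDuplicated(tax$asv_id)) {
    stop("duplicated asv_id in taxonomy", call. = FALSE)
  }
  for (j in ranks) tax[[j]][is.na(tax[[j]])] <- ""
  # lineage must be a prefix: no named rank below a missing one
  if (length(ranks) > 1) {
    for (i in seq_len(nrow(tax))) {
      vals <- vapply(ranks, function(r) tax[[r]][i], character(1))
      empt <- !nzchar(vals)
      if (any(empt) && any(nzchar(vals[seq(which(empt)[1], length(vals))]))) {
        stop("taxonomy row for ", tax$asv_id[i],
             ": rank present below a missing rank", call. = FALSE)
      }
    }
  }
  tax
}

#' Aggregate ASV relative abundances to a taxonomic rank
#'
#' Each taxon's proportion in a sample is the sum of the relative abundances
#' of its member ASVs. ASVs whose lineage is missing at the requested rank
#' are bucketed as `"unclassified_<nearest named parent>"`. When `asv_subset`
#' is given (e.g. the ASVs uniquely identified in the donor input from
#' [unique_input_asvs()]), the rollup is restricted to that subset, so row
#' sums equal that subset's share of each sample rather than 1.
#'
#' @param table a [count_table()].
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()]).
#' @param rank one of kingdom, phylum, class, order, family, genus.
#' @param asv_subset optional character vector of ASV ids to restrict to.
#' @return A `rank_table`: samples x taxa matrix of proportions with
#'   attributes `rank` and `filtered`; taxa ordered by grand-mean proportion
#'   descending, ties broken lexicographically.
#' @export
rollup <- function(table, taxonomy, rank, asv_subset = NULL) {
  if (!rank %in% RANK_LEVELS) {
    stop("unknown rank '", rank, "'; expected one of ",
         paste(RANK_LEVELS, collapse = ", "), call. = FALSE)
  }
  taxonomy <- validate_taxonomy(taxonomy)
  prop <- relative_abundance(table)
  asvs <- colnames(prop)
  if (!is.null(asv_subset)) {
    asv_subset <- intersect(asvs, asv_subset)
    prop <- prop[, asv_subset, drop = FALSE]
    asvs <- asv_subset
  }
  labels <- taxon_labels(taxonomy, asvs, rank)
  taxa <- sort(unique(labels))
  agg <- vapply(taxa, function(tx) {
    rowSums(prop[, labels == tx, drop = FALSE])
  }, numeric(nrow(prop)))
  if (nrow(prop) == 1) agg <- matrix(agg, nrow = 1, dimnames = list(rownames(prop), taxa))
  ord <- order(-colMeans(agg), colnames(agg))
  agg <- agg[, ord, drop = FALSE]
  structure(agg, rank = rank, filtered = !is.null(asv_subset),
            class = c("rank_table", class(agg)))
}

taxon_labels <- function(taxonomy, asvs, rank) {
  idx <- match(asvs, taxonomy$asv_id)
  ranks_present <- intersect(RANK_LEVELS, names(taxonomy))
  upto <- ranks_present[seq_len(match(rank, ranks_present, nomatch = 0L))]
  vapply(seq_along(asvs), function(k) {
    i <- idx[k]
    if (is.na(i)) return("unclassified")
    val <- if (rank %in% names(taxonomy)) taxonomy[[rank]][i] else ""
    if (nzchar(val)) return(val)
    # fall back to the nearest named parent rank
    parents <- rev(upto[-length(upto)])
    for (r in parents) {
      pv <- taxonomy[[r]][i]
      if (nzchar(pv)) return(paste0("unclassified_", pv))
    }
    "unclassified"
  }, character(1))
}

#' Keep the k most abundant taxa, collapsing the rest into "Other"
#'
#' @param rank_table output of [rollup()].
#' @param k number of taxa to retain (by grand-mean proportion).
#' @return A `rank_table` with at most `k + 1` columns; row sums unchanged.
#' @export
top_taxa <- function(rank_table, k) {
  stopifnot(k >= 1)
  atts <- attributes(rank_table)
  m <- unclass(rank_table)
  if (ncol(m) <= k) {
    other <- matrix(0, nrow(m), 1, dimnames = list(rownames(m), "Other"))
    out <- cbind(m, other)
  } else {
    keep <- m[, seq_len(k), drop = FALSE]   # already sorted by grand mean
    other <- rowSums(m[, -seq_len(k), drop = FALSE])
    out <- cbind(keep, Other = other)
  }
  structure(out, rank = atts$rank, filtered = atts$filtered,
            class = c("rank_table", "matrix", "array"))
}
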