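#' Read a metabolite intensity table from TSV
#'
#' Samples x metabolites, non-negative real intensities in arbitrary ion-count
#' units (e.g. a short-chain fatty acid panel: acetate, propionate, butyrate,
#' valerate, caproate, 2-methylbutyrate). Header row holds metabolite names,
#' first column sample ids.
#'
#' @param path TSV path.
#' @return Numeric matrix (samples x metabolites).
#' @export
read_metabolite_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- as.character(raw[[1]])
  validate_metabolite_table(mat)
}

#' Write a metabolite table to TSV
#' @param table metabolite matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_metabolite_table <- function(mat) {
  if (anyDuplicated(colnames(mat))) stop("duplicated metabolite name", call. = FALSE)
  if (anyDuplicated(rownames(mat))) stop("duplicated sample id", call. = FALSE)
  if (!is.numeric(mat) || anyNA(mat)) stop("intensities must be numeric, no NA",
                                           call. = FALSE)
  if (any(mat < 0)) stop("intensities must be non-negative", call. = FALSE)
  mat
}

#' Total-ion-chromatogram (TIC) normalization
#'
#' Divides each intensity by its sample's total signal so that rows sum to
#' one, correcting for per-injection differences in total metabolite load.
#' Idempotent and invariant to per-sample rescaling.
#'
#' @param table metabolite matrix (samples x metabolites).
#' @return Matrix of TIC-normalized intensities.
#' @export
tic_normalize <- function(table) {
  table <- validate_metabolite_table(as.matrix(table))
  totals <- rowSums(table)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(rownames(table)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  table / totals
}

#' Average technical replicates
#'
#' Arithmetic mean per metabolite over each replicate group (e.g. donor
#' aliquots injected in triplicate); samples not listed pass through
#' unchanged. Intended to run after [tic_normalize()]: normalization is a
#' per-injection correction, averaging a per-biological-source summary, and
#' the two operations do not commute when replicate totals differ.
#'
#' @param table metabolite matrix.
#' @param replicate_groups named list: new sample id -> character vector of
#'   replicate sample ids to average.
#' @return Metabolite matrix with each replicate group collapsed to one row.
#' @export
average_replicates <- function(table, replicate_groups) {
  table <- as.matrix(table)
  used <- character(0)
  rows <- list()
  for (nm in names(replicate_groups)) {
    ids <- replicate_groups[[nm]]
    if (!length(ids)) stop("empty replicate group: ", nm, call. = FALSE)
    missing <- setdiff(ids, rownames(table))
    if (length(missing)) {
      stop("replicate sample(s) not in table: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    rows[[nm]] <- colMeans(table[ids, , drop = FALSE])
    used <- c(used, ids)
  }
  passthrough <- table[setdiff(rownames(table), used), , drop = FALSE]
  avg <- do.call(rbind, rows)
  out <- rbind(avg, passthrough)
  validate_metabolite_table(out)
}

#' Principal component analysis of a metabolite table
#'
#' Column-centered (and by default unit-variance scaled, since metabolite
#' intensities span orders of magnitude) singular value decomposition.
#' Loadings columns are orthonormal; for a deterministic sign convention the
#' largest-magnitude element of each loading column is made positive.
#'
#' @param table metabolite matrix (samples x metabolites), typically
#'   TIC-normalized.
#' @param center center columns (default `TRUE`).
#' @param scale scale columns to unit variance (default `TRUE`).
#' @return A `pca_result` list: `scores` (samples x components), `loadings`
#'   (metabolites x components), `explained_variance_ratio`, `center`,
#'   `scale`.
#' @export
metabolite_pca <- function(table, center = TRUE, scale = TRUE) {
  x <- as.matrix(table)
  if (nrow(x) < 2 || ncol(x) < 2) stop("PCA needs >= 2 samples and >= 2 metabolites",
                                       call. = FALSE)
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance metabolite(s) with scale=TRUE: ",
           paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  xc <- scale(x, center = center, scale = scale)
  sv <- svd(xc)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  u <- sv$u[, seq_len(ncomp), drop = FALSE]
  v <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest |loading| per component positive
  flip <- vapply(seq_len(ncomp), function(j) {
    sign(v[which.max(abs(v[, j])), j])
  }, numeric(1))
  v <- sweep(v, 2, flip, `*`)
  u <- sweep(u, 2, flip, `*`)
  scores <- u %*% diag(d, ncomp)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
  structure(list(scores = scores, loadings = v,
                 explained_variance_ratio = d^2 / sum(sv$d^2),
                 center = center, scale = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat(sprintf("PCA: %d samples, %d metabolites; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings), 100 * evr[1],
              if (length(evr) > 1) 100 * evr[2] else 0))
  invisible(x)
}
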