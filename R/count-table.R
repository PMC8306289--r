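#' Construct an ASV count table
#'
#' The central data object of the package: a samples x ASVs matrix of
#' non-negative integer read counts. Rows are samples, columns are amplicon
#' sequence variants (ASVs). Counts are kept as integers; proportions are
#' derived on demand with [relative_abundance()] and never stored, which
#' prevents silent double-normalization.
#'
#' @param counts integer matrix, samples x ASVs, all entries >= 0.
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to `rownames(counts)`).
#' @param asv_ids character vector of unique ASV identifiers
#'   (defaults to `colnames(counts)`).
#' @return A `count_table` object: an integer matrix with class
#'   `"count_table"`, dimnames `sample_ids` x `asv_ids`.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        asv_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(asv_ids)) {
    stop("count_table requires sample and ASV identifiers", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  asv_ids <- as.character(asv_ids)
  if (length(sample_ids) != nrow(counts) || length(asv_ids) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  dup_a <- asv_ids[duplicated(asv_ids)]
  if (length(dup_a)) {
    stop("duplicated ASV id(s): ", paste(unique(dup_a), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(counts) || !is.numeric(counts)) {
    stop("counts must be numeric with no missing values", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, asv_ids)
  class(counts) <- c("count_table", class(counts))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("ASV count table: %d samples x %d ASVs, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read an ASV count table from TSV
#'
#' Expects a tab-separated file whose header row holds ASV ids and whose
#' first column holds sample ids.
#'
#' @param path path to a TSV file.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs a sample-id column plus >= 1 ASV column",
                          call. = FALSE)
  header <- scan(path, what = character(), nlines = 1, sep = "\t",
                 quiet = TRUE)
  asv_ids <- header[-1]
  dup <- asv_ids[duplicated(asv_ids)]
  if (length(dup)) {
    stop("duplicated ASV id(s) in header: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count cell(s)", call. = FALSE)
  count_table(mat, sample_ids = sample_ids, asv_ids = asv_ids)
}

#' Write an ASV count table to TSV
#'
#' @param table a [count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table),
                   unclass(table)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total so rows sum to one. The zero
#' pattern of the counts is preserved.
#'
#' @param table a [count_table()] (or any samples x taxa numeric matrix).
#' @return A numeric matrix of proportions with the same dimnames.
#' @export
relative_abundance <- function(table) {
  m <- unclass(as.matrix(table))
  storage.mode(m) <- "double"
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    bad <- rownames(m)[totals <= 0]
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m / totals
}
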