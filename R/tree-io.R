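#' Read a rooted phylogenetic tree from a Newick file
#'
#' Trees are handled as `ape::phylo` objects. UniFrac needs a rooted tree
#' with non-negative branch lengths and uniquely labeled leaves; unrooted
#' input is midpoint-rooted deterministically (with a message) so that the
#' branch partition underlying UniFrac is well defined.
#'
#' @param path path to a Newick file.
#' @param root if `TRUE` (default) midpoint-root unrooted input;
#'   if `FALSE`, unrooted input is an error.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path, root = TRUE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  validate_tree(tree, root = root)
}

#' Write a tree to a Newick file
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree, root = TRUE) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree has missing or negative branch lengths", call. = FALSE)
  }
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("tree has unlabeled leaves", call. = FALSE)
  if (anyDuplicated(labs)) {
    stop("duplicated leaf label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    if (!root) stop("tree is unrooted", call. = FALSE)
    if (!requireNamespace("phangorn", quietly = TRUE)) {
      stop("tree is unrooted and phangorn is unavailable for midpoint rooting",
           call. = FALSE)
    }
    message("input tree is unrooted; midpoint-rooting it")
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Total branch length of a tree
#' @param tree an `ape::phylo` object.
#' @return Sum of all branch lengths.
#' @export
total_branch_length <- function(tree) sum(tree$edge.length)
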