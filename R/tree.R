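#' Read a dated phylogeny from Newick
#'
#' Parses a Newick string (or file) into an `ape::phylo` tree, validates
#' that every edge carries a nonnegative branch length (interpreted in
#' millions of years), and optionally enforces ultrametricity: all tips at
#' age 0 within a tolerance. Polytomies are allowed and kept as-is.
#'
#' @param x Newick string, or path to a file containing one.
#' @param ultrametric logical; if `TRUE`, require all tips to be
#'   contemporaneous (age 0) within `tol`.
#' @param tol tolerance for the ultrametricity check, in My. Defaults to
#'   `1e-6` times the root age.
#' @return an object of class `phylo` with branch lengths in My.
#' @seealso [node_ages()], [write_newick()]
#' @export
read_newick <- function(x, ultrametric = FALSE, tol = NULL) {
  phy <- if (length(x) == 1L && !grepl("\\(", x) && file.exists(x)) {
    ape::read.tree(x)
  } else {
    ape::read.tree(text = x)
  }
  if (is.null(phy)) stop("malformed Newick string: could not be parsed")
  validate_dated_tree(phy)
  if (ultrametric) {
    ages <- node_ages(phy)
    tip_ages <- ages[seq_len(ape::Ntip(phy))]
    if (is.null(tol)) tol <- 1e-6 * max(ages)
    bad <- which(abs(tip_ages) > tol)
    if (length(bad) > 0L) {
      stop("tree is not ultrametric: tip(s) ",
           paste(phy$tip.label[head(bad, 5L)], collapse = ", "),
           " end at age > ", format(tol), " My before present")
    }
  }
  phy
}

#' Write a tree to Newick
#'
#' @param phy a `phylo` tree.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(phy, file = NULL) {
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

validate_dated_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' tree")
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; dated branch lengths in My are required")
  }
  if (anyNA(phy$edge.length)) stop("tree has missing branch lengths")
  neg <- which(phy$edge.length < 0)
  if (length(neg) > 0L) {
    child <- phy$edge[neg[1L], 2L]
    lab <- if (child <= ape::Ntip(phy)) phy$tip.label[child] else
      paste0("internal node ", child)
    stop("negative branch length on the edge above ", lab)
  }
  if (anyDuplicated(phy$tip.label)) stop("tip labels are not unique")
  invisible(TRUE)
}

#' Node ages of a dated tree
#'
#' Ages are measured backward from the youngest tip: the youngest tip has
#' age 0 and the root has the largest age. Nodes are indexed in `ape`
#' order: tips `1..n`, then internal nodes `n+1..2n-1` (root first).
#'
#' @param phy a `phylo` tree with branch lengths in My.
#' @return numeric vector of ages (My) for every node.
#' @export
node_ages <- function(phy) {
  validate_dated_tree(phy)
  depth <- ape::node.depth.edgelength(phy)
  max(depth[seq_len(ape::Ntip(phy))]) - depth
}
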