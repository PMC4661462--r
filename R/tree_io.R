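#' Validate a phylogeny for diversity calculations
#'
#' Checks the contract every phylogeny-consuming operation relies on: a
#' rooted `phylo` tree, unique tip labels, and finite non-negative branch
#' lengths on every edge. Missing branch lengths are an error rather than
#' being defaulted to zero, because UniFrac and Faith's PD are undefined
#' without them.
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly, if valid.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it (e.g. with an outgroup or midpoint ",
         "rooting) before use", call. = FALSE)
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("missing branch lengths; lengths are required on every edge",
         call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative", call. = FALSE)
  invisible(tree)
}

#' Read a rooted, branch-lengthed Newick tree
#'
#' @param path Newick file path.
#' @return A validated [ape::phylo] tree.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file", call. = FALSE)
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny as Newick
#'
#' Round-trips preserve the tip set exactly and total branch length to
#' better than 1e-9.
#'
#' @param tree A validated [ape::phylo] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
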