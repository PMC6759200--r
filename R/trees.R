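#' Read a rooted Newick tree
#'
#' Loss inference under Dollo parsimony needs a root, so trees whose root
#' is a trifurcation (ape's representation of an unrooted tree) are
#' rejected with an instruction to root them first.
#'
#' @param path Path to a file containing a single Newick tree.
#' @return An \link[ape]{ape} \code{phylo} object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file does not exist: ", path)
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1]]
  }
  if (is.null(tr)) stop("could not parse Newick tree from ", path)
  check_rooted(tr)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' @noRd
check_rooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted (root is a multifurcation of an unrooted tree); ",
         "root it (e.g. with ape::root on an outgroup) before use")
  }
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree A \code{phylo} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
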