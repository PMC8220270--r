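#' @include measurements.R
NULL

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' downstream comparative analyses need: a single rooted tree with branch
#' lengths, finite and nonnegative.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
readTreeFile <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo"))
    stop("'", path, "' contains more than one tree")
  if (is.null(tr)) stop("could not parse a tree from '", path, "'")
  .checkTree(tr)
  tr
}

.checkTree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a 'phylo' tree")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be finite and nonnegative")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  invisible(tr)
}

#' Prune a phylogeny to a set of species
#'
#' Keeps exactly the requested tips; the induced topology and all path
#' lengths among the kept tips are preserved (patristic distances are
#' unchanged). Requesting a tip absent from the tree is an error that names
#' the offenders.
#'
#' @param tree an [ape::phylo] tree.
#' @param species character vector of tip labels to retain (2 or more).
#' @return the pruned [ape::phylo] tree.
#' @export
pruneTreeTo <- function(tree, species) {
  .checkTree(tree)
  species <- unique(as.character(species))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
  if (length(species) < 2L)
    stop("need at least two tips after pruning")
  if (length(species) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, species)
}

#' Brownian-motion covariance implied by a phylogeny
#'
#' `C[i, j]` is the shared path length from the root to the most recent
#' common ancestor of tips `i` and `j`; diagonal entries are root-to-tip
#' depths. This is the among-species covariance structure of a trait
#' evolving by Brownian motion on the tree, the weighting used by
#' [phyloPCA()].
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @return symmetric positive semidefinite matrix with tip-label dimnames.
#' @export
phyloVCV <- function(tree) {
  .checkTree(tree)
  ape::vcv.phylo(tree)
}
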