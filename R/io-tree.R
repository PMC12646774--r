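#' Read a rooted phylogeny with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]. The comparative
#' machinery downstream (Brownian covariances, Pagel's lambda, PGLS, the
#' phylogenetic mixed model) requires a rooted tree with a branch length
#' on every edge and unique tip labels, so these are enforced at read time
#' rather than deep inside a model fit.
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_fmt("could not parse Newick in %s", path)
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree an [ape::phylo] object to validate in memory.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_fmt("'tree' must be a phylo object")
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) seq_len(nrow(tree$edge))
           else which(is.na(tree$edge.length))
    stop_fmt("missing branch length on edge(s): %s",
             paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(tree$edge.length < 0))
    stop_fmt("negative branch length on edge %s",
             which(tree$edge.length < 0)[1L])
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop_fmt("duplicate tip label(s): %s", paste(dup, collapse = ", "))
  # a basal trifurcation on an otherwise binary tree is the canonical
  # unrooted representation; genuine polytomies (e.g. star trees) pass
  if (!ape::is.rooted(tree) && ape::is.binary(tree))
    stop_fmt("tree must be rooted")
  tree
}

#' Write a phylogeny as Newick
#'
#' @param tree an [ape::phylo] object.
#' @param path output file.
#' @param digits branch-length precision passed to [ape::write.tree()].
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, digits = 17) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
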