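#' Neighbor-joining tree from a distance table
#'
#' Standard neighbor joining (Q-criterion agglomeration, via
#' [ape::nj()]) on a pairwise distance table or matrix. Negative branch
#' lengths -- a known NJ artefact on noisy matrices -- are clamped to zero,
#' with the count recorded in attribute `n_clamped`. This is the
#' distance-based surrogate this package provides in place of full
#' Bayesian tree inference, which is out of its scope.
#'
#' @param d A `dist_tbl` from [p_distance_matrix()], or a symmetric
#'   numeric matrix with labels.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  m <- if (is.matrix(d)) d else as_dist_matrix(d)
  if (nrow(m) < 3) abort("need at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-8) abort("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(m))
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "n_clamped") <- sum(neg)
  tr
}

#' Newick tree I/O
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()], so
#' externally inferred trees (e.g. a Bayesian consensus tree) can be
#' dropped into the pipeline.
#'
#' @param path File path.
#' @param tree An [ape::phylo] object.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort(paste0("not a valid newick file: ", path))
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Robinson-Foulds distance between two trees
#'
#' The number of bipartitions present in exactly one of the two trees
#' (computed with [phangorn::RF.dist()]). Both trees must share the same
#' leaf set.
#'
#' @param t1,t2 [ape::phylo] trees.
#' @return A non-negative integer; 0 means identical unrooted topologies.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees must share the same leaf set")
  }
  as.integer(phangorn::RF.dist(ape::unroot(ape::collapse.singles(t1)),
                               ape::unroot(ape::collapse.singles(t2))))
}
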