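# bitmask-encoded patterns for parsimony (same IUPAC masks as the
# likelihood engine; fully ambiguous characters never cost a change)
parsimony_patterns <- function(aln) {
  pat <- compress_patterns(aln)
  list(mask = pat$codes, w = pat$w)
}

#' Fitch parsimony score
#'
#' Number of character changes required by a tree under the Fitch criterion,
#' summed over alignment columns. Ambiguity codes contribute their compatible
#' state sets; gaps and `N` are fully ambiguous and never force a change.
#'
#' @param aln a [dna_alignment()].
#' @param tree a `phylo` whose tips all occur in the alignment.
#' @return numeric parsimony score.
#' @export
fitch_score <- function(aln, tree) {
  stopifnot(inherits(aln, "dna_alignment"))
  pp <- parsimony_patterns(aln)
  tree <- prepare_tree(tree, default_bl = 0)
  tt <- tree_tables(tree)
  i <- match(tt$tree$tip.label, rownames(pp$mask))
  if (anyNA(i))
    stop("tree taxa missing from alignment: ",
         paste(tt$tree$tip.label[is.na(i)], collapse = ", "))
  cpp_fitch_score(tt$edge, tt$n_tip, pp$mask[i, , drop = FALSE], pp$w)
}

#' Randomized maximum-parsimony starting tree
#'
#' Stepwise addition in a random taxon order: taxa are shuffled, the first
#' three form the unique unrooted topology, and each remaining taxon is
#' attached on the branch that minimizes the Fitch score (ties broken by the
#' first minimum, so the result is fully determined by the seed).
#'
#' @param aln a [dna_alignment()] with >= 3 taxa.
#' @param seed integer seed for the taxon shuffle; `NULL` uses the current
#'   RNG state.
#' @return an unrooted `phylo` over all alignment taxa, with attribute
#'   `parsimony_score`; branch lengths are set to a small constant as a
#'   starting point for likelihood optimization.
#' @export
parsimony_random_addition_tree <- function(aln, seed = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  taxa <- aln_taxa(aln)
  n <- length(taxa)
  if (n < 3L) stop("need >= 3 taxa")
  pp <- parsimony_patterns(aln)
  ord <- if (is.null(seed)) sample.int(n) else
    with_seed(seed, sample.int(n))
  res <- cpp_parsimony_addition(n, pp$mask, pp$w, as.integer(ord))
  tr <- structure(list(edge = res$edge, Nnode = n - 1L, tip.label = taxa,
                       edge.length = rep(0.05, nrow(res$edge))),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr <- prepare_tree(tr)
  attr(tr, "parsimony_score") <- res$score
  tr
}

# evaluate code under a temporary seed, restoring the RNG state afterwards
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive independent sub-seeds from a top-level seed
#'
#' Every stochastic step in the package (starting trees, bootstrap
#' replicates, subsampling, simulation) receives its own sub-seed drawn from
#' a seed table generated by the top-level seed, so any replicate can be
#' reproduced in isolation.
#'
#' @param seed top-level integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of `n` distinct seeds.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
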