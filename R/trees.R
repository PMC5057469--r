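#' Read and write Newick trees
#'
#' Wrappers around ape's Newick parser. Trees are treated as unrooted;
#' branch lengths are expected substitutions per site. Reading a tree
#' without branch lengths sets them to 0 with a warning. Before writing,
#' the tree is canonicalized (children sorted by their smallest descendant
#' label) so equivalent trees serialize identically.
#'
#' @param path file path.
#' @return [read_newick()] returns a `phylo`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("could not parse Newick file: ", path)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("tree has missing branch lengths; setting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths in ", path)
  tr
}

#' @param tree a `phylo`.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(canonicalize_tree(tree), file = path)
  invisible(path)
}

#' Canonical child order
#'
#' Reorders each internal node's children by the lexicographically smallest
#' tip label in their subtree, so that topologically identical trees produce
#' byte-identical Newick strings.
#'
#' @param tree a `phylo`.
#' @return the tree with edges reordered (cladewise, sorted children).
#' @export
canonicalize_tree <- function(tree) {
  E <- tree$edge
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  kids <- vector("list", n_nodes)
  sp <- split(seq_len(nrow(E)), E[, 1L])
  for (nm in names(sp)) kids[[as.integer(nm)]] <- sp[[nm]]
  minlab <- character(n_nodes)
  fill_min <- function(v) {
    if (v <= n_tip) return(tree$tip.label[v])
    labs <- vapply(E[kids[[v]], 2L], fill_min, "")
    minlab[v] <<- min(labs)
    minlab[v]
  }
  root <- n_tip + 1L
  fill_min(root)
  order_edges <- integer(0)
  emit <- function(v) {
    if (v <= n_tip) return(invisible(NULL))
    es <- kids[[v]]
    labs <- vapply(E[es, 2L], function(u)
      if (u <= n_tip) tree$tip.label[u] else minlab[u], "")
    for (e in es[order(labs)]) {
      order_edges <<- c(order_edges, e)
      emit(E[e, 2L])
    }
  }
  emit(root)
  tree$edge <- E[order_edges, , drop = FALSE]
  if (!is.null(tree$edge.length))
    tree$edge.length <- tree$edge.length[order_edges]
  attr(tree, "order") <- "cladewise"
  tree
}

#' Total tree length
#'
#' Sum of all branch lengths, in expected substitutions per site; invariant
#' to rooting.
#'
#' @param tree a `phylo` with branch lengths.
#' @return numeric scalar >= 0.
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

#' Bipartitions (splits) of an unrooted tree
#'
#' Every internal branch splits the taxon set in two. Splits are stored
#' canonically as the smaller side with sorted labels (ties between
#' equal-sized sides broken lexicographically); only informative splits
#' (both sides >= 2 taxa) are returned.
#'
#' @param tree a `phylo`.
#' @return character vector of split keys (labels joined by `;`).
#' @export
bipartitions <- function(tree) {
  tree <- ape::reorder.phylo(prepare_tree(tree, default_bl = 0),
                             "postorder")
  E <- tree$edge
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  below <- vector("list", n_nodes)
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  labels <- tree$tip.label
  all_idx <- seq_len(n_tip)
  for (e in seq_len(nrow(E))) {
    ch <- E[e, 2L]
    if (ch <= n_tip) next
    side <- below[[ch]]
    if (length(side) < 2L || n_tip - length(side) < 2L) next
    keys <- c(keys, split_key(labels[side], labels[setdiff(all_idx, side)]))
  }
  unique(keys)
}

split_key <- function(side_a, side_b) {
  a <- sort(side_a); b <- sort(side_b)
  if (length(a) < length(b)) return(paste(a, collapse = ";"))
  if (length(b) < length(a)) return(paste(b, collapse = ";"))
  ka <- paste(a, collapse = ";"); kb <- paste(b, collapse = ";")
  if (ka <= kb) ka else kb
}

#' Bootstrap support for a reference tree's bipartitions
#'
#' For each informative bipartition of `ref_tree`, the percentage of trees
#' in `tree_sample` whose bipartition set contains it.
#'
#' @param ref_tree reference `phylo`.
#' @param tree_sample list of `phylo` objects on the same taxon set.
#' @return named numeric vector of support percentages in `[0, 100]`, one
#'   entry per internal bipartition of `ref_tree`.
#' @export
bipartition_support <- function(ref_tree, tree_sample) {
  ref_taxa <- sort(ref_tree$tip.label)
  for (tr in tree_sample)
    if (!identical(sort(tr$tip.label), ref_taxa))
      stop("all trees must share the reference taxon set")
  ref <- bipartitions(ref_tree)
  counts <- setNames(numeric(length(ref)), ref)
  for (tr in tree_sample) {
    hit <- ref %in% bipartitions(tr)
    counts[hit] <- counts[hit] + 1
  }
  100 * counts / length(tree_sample)
}

#' Enumerate all unrooted binary topologies
#'
#' Exhaustive enumeration by stepwise addition on every edge; there are
#' (2n-5)!! topologies for n taxa, so this is intended for small n (<= 8).
#'
#' @param taxa character vector of >= 3 labels.
#' @return list of unrooted `phylo` objects without branch lengths.
#' @export
all_unrooted_topologies <- function(taxa) {
  n <- length(taxa)
  if (n < 3L) stop("need >= 3 taxa")
  if (n > 8L) stop("refusing to enumerate ", n, " taxa (too many topologies)")
  # topologies as nested lists rooted at the basal trifurcation; every list
  # slot (a subtree hanging on an edge) is an insertion point
  insert_everywhere <- function(node, tip) {
    out <- list()
    for (i in seq_along(node)) {
      replaced <- node
      replaced[[i]] <- list(node[[i]], tip)
      out <- c(out, list(replaced))
      if (is.list(node[[i]])) {
        for (sub in insert_everywhere(node[[i]], tip)) {
          deeper <- node
          deeper[[i]] <- sub
          out <- c(out, list(deeper))
        }
      }
    }
    out
  }
  to_newick <- function(node) {
    if (!is.list(node)) return(node)
    paste0("(", paste(vapply(node, to_newick, ""), collapse = ","), ")")
  }
  shapes <- list(list(taxa[1], taxa[2], taxa[3]))
  for (k in seq(4L, length.out = max(0L, n - 3L)))
    shapes <- unlist(lapply(shapes, insert_everywhere, tip = taxa[k]),
                     recursive = FALSE)
  lapply(shapes, function(s)
    ape::read.tree(text = paste0(to_newick(s), ";")))
}
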