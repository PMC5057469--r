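#' Relative evolutionary rate of one gene
#'
#' With the topology and the substitution-model parameters fixed at the
#' values estimated from the concatenated data, branch lengths are
#' re-optimized on the gene alignment alone; the gene's relative rate is
#' its tree length divided by the tree length of the concatenated-data
#' tree. Rates above 1 mark genes evolving faster than the genome-wide
#' coding average, below 1 slower. Taxa lacking the gene are pruned first,
#' and the concatenated tree length used in the denominator is taken from
#' the tree pruned to the same taxa, so missing taxa do not deflate the
#' ratio.
#'
#' @param gene_aln a [dna_alignment()] for one gene (taxa a subset of the
#'   tree's tips).
#' @param concat_tree the ML tree of the concatenated data, with optimized
#'   branch lengths.
#' @param model the GTR+Gamma model optimized on the concatenated data.
#' @param name gene name used in the record.
#' @param min_taxa genes with fewer taxa (after pruning) are flagged
#'   uncomputable.
#' @param bl_tol branch-length convergence tolerance.
#' @return one-row `data.frame`: `gene`, `length`, `n_taxa`,
#'   `gene_tree_length`, `concat_tree_length`, `relative_rate`,
#'   `computable`.
#' @export
relative_gene_rate <- function(gene_aln, concat_tree, model,
                               name = "gene", min_taxa = 4L,
                               bl_tol = 1e-3) {
  stopifnot(inherits(gene_aln, "dna_alignment"))
  concat_tree <- prepare_tree(concat_tree)
  taxa_g <- intersect(taxa_with_data(gene_aln), concat_tree$tip.label)
  rec <- data.frame(gene = name, length = aln_nsites(gene_aln),
                    n_taxa = length(taxa_g),
                    gene_tree_length = NA_real_,
                    concat_tree_length = NA_real_,
                    relative_rate = NA_real_, computable = FALSE,
                    stringsAsFactors = FALSE)
  if (length(taxa_g) < min_taxa) return(rec)
  tr <- concat_tree
  if (length(taxa_g) < length(tr$tip.label))
    tr <- ape::drop.tip(tr, setdiff(tr$tip.label, taxa_g))
  denom <- tree_length(tr)
  sub <- gene_aln
  sub$seq <- sub$seq[taxa_g, , drop = FALSE]
  fit <- optimize_branch_lengths(sub, tr, model, tol = bl_tol,
                                 max_rounds = 25L, ttol = 1e-6)
  rec$gene_tree_length <- tree_length(fit)
  rec$concat_tree_length <- denom
  rec$relative_rate <- rec$gene_tree_length / denom
  rec$computable <- TRUE
  rec
}

#' Relative rates for every gene of a partitioned alignment
#'
#' @param aln the concatenated, partitioned [dna_alignment()].
#' @param concat_tree,model as in [relative_gene_rate()].
#' @param ... passed on to [relative_gene_rate()].
#' @return a `data.frame` with one row per gene (class
#'   `gene_rate_table`).
#' @export
relative_gene_rates <- function(aln, concat_tree, model, ...) {
  genes <- split_genes(aln)
  recs <- lapply(names(genes), function(g)
    relative_gene_rate(genes[[g]], concat_tree, model, name = g, ...))
  out <- do.call(rbind, recs)
  class(out) <- c("gene_rate_table", "data.frame")
  out
}

#' Partition genes into rate categories
#'
#' Genes shorter than `min_length` are excluded; the rest are labelled
#' `slow` (rate < `lo`), `fast` (rate > `hi`) or `medium` (rates in the
#' closed interval `[lo, hi]`, so boundary values are medium). Genes whose
#' rate could not be computed are excluded as well.
#'
#' @param records a `data.frame` from [relative_gene_rates()].
#' @param min_length minimum gene length in nt.
#' @param lo,hi relative-rate thresholds.
#' @return the records with an added `category` column (factor with levels
#'   slow, medium, fast, excluded).
#' @export
categorize_genes <- function(records, min_length = 800L, lo = 0.75,
                             hi = 1.5) {
  stopifnot(lo < hi)
  cat <- rep("excluded", nrow(records))
  ok <- records$computable & !is.na(records$relative_rate) &
    records$length >= min_length
  r <- records$relative_rate
  cat[ok & r < lo] <- "slow"
  cat[ok & r >= lo & r <= hi] <- "medium"
  cat[ok & r > hi] <- "fast"
  records$category <- factor(cat,
                             levels = c("slow", "medium", "fast", "excluded"))
  records
}

#' Concatenate the genes of one rate category
#'
#' @param gene_alignments named list of gene alignments (names matching
#'   `records$gene`).
#' @param records categorized records from [categorize_genes()].
#' @param category one of `"slow"`, `"medium"`, `"fast"`.
#' @return a partitioned [dna_alignment()] of the category's genes.
#' @export
concatenate_category <- function(gene_alignments, records, category) {
  category <- match.arg(category, c("slow", "medium", "fast"))
  sel <- records$gene[records$category == category]
  if (!length(sel))
    stop("no genes in category '", category, "'")
  concatenate(gene_alignments[sel])
}
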