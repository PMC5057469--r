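#' Filter genes by taxon occupancy
#'
#' Keeps genes present in at least `min_taxa` taxa. A taxon counts as
#' present when its row contains at least one unambiguous nucleotide. The
#' default (7) retains genes present in more than 6 taxa.
#'
#' @param gene_alignments named list of [dna_alignment()] objects.
#' @param min_taxa minimum number of taxa with data (>= 1).
#' @return the filtered (possibly empty) list.
#' @export
filter_genes_by_taxa <- function(gene_alignments, min_taxa = 7L) {
  stopifnot(min_taxa >= 1L)
  keep <- vapply(gene_alignments,
                 function(g) length(taxa_with_data(g)) >= min_taxa, TRUE)
  gene_alignments[keep]
}

#' Concatenate gene alignments
#'
#' Stacks gene alignments side by side over the union of their taxa; taxa
#' absent from a gene are filled with gaps. The result carries a partition
#' map recording each gene's column interval.
#'
#' @param gene_alignments named list of [dna_alignment()] objects (names
#'   become partition names).
#' @return a partitioned [dna_alignment()].
#' @export
concatenate <- function(gene_alignments) {
  if (!length(gene_alignments)) stop("no gene alignments to concatenate")
  if (is.null(names(gene_alignments)) || any(!nzchar(names(gene_alignments))))
    names(gene_alignments) <- sprintf("gene%03d",
                                      seq_along(gene_alignments))
  taxa <- sort(unique(unlist(lapply(gene_alignments,
                                    function(g) rownames(g$seq)))))
  lens <- vapply(gene_alignments, aln_nsites, 0L)
  total <- sum(lens)
  m <- matrix("-", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  ends <- cumsum(lens)
  starts <- ends - lens
  for (i in seq_along(gene_alignments)) {
    g <- gene_alignments[[i]]
    m[rownames(g$seq), (starts[i] + 1L):ends[i]] <- g$seq
  }
  parts <- data.frame(name = names(gene_alignments),
                      start = as.integer(starts), end = as.integer(ends),
                      stringsAsFactors = FALSE)
  dna_alignment(m, partitions = parts)
}

# per-column tallies of unambiguous bases: n_sites x 4 matrix
base_tallies <- function(aln) {
  m <- aln$seq
  tal <- vapply(.base_chars, function(b) colSums(m == b), numeric(ncol(m)))
  matrix(tal, ncol = 4L)
}

#' Variable and parsimony-informative sites
#'
#' A column is variable when it shows at least two distinct unambiguous
#' nucleotides, and parsimony-informative when at least two nucleotides each
#' occur in at least two taxa. Gaps and ambiguity codes are ignored in both
#' tallies.
#'
#' @param aln a [dna_alignment()].
#' @return an integer count.
#' @export
count_variable_sites <- function(aln) {
  tal <- base_tallies(aln)
  sum(rowSums(tal > 0) >= 2L)
}

#' @rdname count_variable_sites
#' @export
count_parsimony_informative <- function(aln) {
  tal <- base_tallies(aln)
  sum(rowSums(tal >= 2L) >= 2L)
}

#' Descriptive alignment summary
#'
#' Counts and percentages of variable and parsimony-informative sites:
#' `pct_variable` is 100 * variable / columns and
#' `pct_informative_of_variable` is 100 * informative / variable (0, with a
#' flag, when nothing varies). Percentages are stored at full precision;
#' see [format_percent()] for display conventions.
#'
#' @param aln a [dna_alignment()].
#' @return a list of class `alignment_summary`.
#' @export
summarize_alignment <- function(aln) {
  n_var <- count_variable_sites(aln)
  n_inf <- count_parsimony_informative(aln)
  alignment_percentages(aln_nsites(aln), n_var, n_inf,
                        n_taxa = nrow(aln$seq))
}

#' @rdname summarize_alignment
#' @param n_columns,n_variable,n_informative counts, e.g. from a published
#'   table, from which the percentages are recomputed.
#' @param n_taxa optional taxon count carried through to the summary.
#' @export
alignment_percentages <- function(n_columns, n_variable, n_informative,
                                  n_taxa = NA_integer_) {
  stopifnot(n_informative <= n_variable, n_variable <= n_columns)
  structure(list(
    n_taxa = n_taxa,
    n_columns = n_columns,
    n_variable = n_variable,
    pct_variable = 100 * n_variable / n_columns,
    n_parsimony_informative = n_informative,
    pct_informative_of_variable =
      if (n_variable > 0) 100 * n_informative / n_variable else 0,
    no_variation = n_variable == 0
  ), class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("alignment of %s taxa, %d columns\n",
              ifelse(is.na(x$n_taxa), "?", x$n_taxa), x$n_columns))
  cat(sprintf("  variable sites: %d (%s%%)\n", x$n_variable,
              format_percent(x$pct_variable, 1)))
  cat(sprintf("  parsimony-informative: %d (%s%% of variable)\n",
              x$n_parsimony_informative,
              format_percent(x$pct_informative_of_variable, 1)))
  if (x$no_variation) cat("  [no variation in the alignment]\n")
  invisible(x)
}

#' Percentage display conventions
#'
#' Published percentages are sometimes truncated rather than rounded; both
#' conventions are provided. `"round"` is round-half-up at `digits`
#' decimals, `"trunc"` drops the remaining decimals.
#'
#' @param x percentage value.
#' @param digits decimal places.
#' @param convention `"round"` or `"trunc"`.
#' @return formatted character scalar.
#' @export
format_percent <- function(x, digits = 1, convention = c("round", "trunc")) {
  convention <- match.arg(convention)
  f <- 10^digits
  v <- if (convention == "round") floor(x * f + 0.5) / f else
    trunc(x * f) / f
  formatC(v, format = "f", digits = digits)
}
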