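#' Multiple sequence alignment of nucleotide data
#'
#' `dna_alignment()` builds the package's alignment container from a character
#' matrix (taxa in rows) or a named character vector of equal-length strings.
#' Characters are stored upper-case and must belong to the DNA alphabet:
#' `A C G T`, the IUPAC ambiguity codes, the gap `-`, or `?` (treated like
#' `N`, i.e. fully missing).
#'
#' @param x character matrix (rows = taxa, columns = sites, rownames = taxon
#'   labels) or a named character vector of sequences.
#' @param partitions optional `data.frame` with columns `name`, `start`,
#'   `end` describing gene blocks in 0-based half-open coordinates (see
#'   [read_partitions()] for the 1-based on-disk convention).
#' @return an object of class `dna_alignment`: a list with elements `seq`
#'   (character matrix) and `partitions` (`data.frame` or `NULL`).
#' @examples
#' aln <- dna_alignment(c(t1 = "ACGT", t2 = "ACGA"))
#' aln
#' @export
dna_alignment <- function(x, partitions = NULL) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(x, ""))
    rownames(mat) <- names(x)
    x <- mat
  }
  if (!is.matrix(x) || !is.character(x)) stop("'x' must be a character matrix")
  if (is.null(rownames(x))) stop("alignment rows must be named by taxon")
  x[] <- toupper(x)
  aln <- structure(list(seq = x, partitions = NULL), class = "dna_alignment")
  validate_alignment(aln)
  if (!is.null(partitions)) aln <- set_partitions(aln, partitions)
  aln
}

validate_alignment <- function(aln) {
  m <- aln$seq
  taxa <- rownames(m)
  if (nrow(m) < 2L) stop("alignment must contain at least 2 taxa")
  if (anyDuplicated(taxa))
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  bad <- matrix(!(m %in% names(.iupac_bits)), nrow(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("illegal character '%s' for taxon '%s' at column %d",
                 m[idx[1L], idx[2L]], taxa[idx[1L]], idx[2L]))
  }
  invisible(aln)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa, %d sites\n", nrow(x$seq), ncol(x$seq)))
  if (!is.null(x$partitions))
    cat(sprintf("  %d gene partitions\n", nrow(x$partitions)))
  cat("  taxa:", paste(head(rownames(x$seq), 6L), collapse = ", "),
      if (nrow(x$seq) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Alignment dimensions and labels
#'
#' @param aln a [dna_alignment()].
#' @return `aln_taxa()` the taxon labels; `aln_nsites()` the number of
#'   columns.
#' @export
aln_taxa <- function(aln) rownames(aln$seq)

#' @rdname aln_taxa
#' @export
aln_nsites <- function(aln) ncol(aln$seq)

# columns subset, keeping class; partitions are dropped (they would no longer
# describe contiguous blocks)
aln_subset_cols <- function(aln, cols) {
  structure(list(seq = aln$seq[, cols, drop = FALSE], partitions = NULL),
            class = "dna_alignment")
}

#' Taxa that carry data in an alignment
#'
#' A taxon "has" a gene when its row contains at least one unambiguous
#' nucleotide; rows of pure gaps/`N`/`?` count as missing.
#'
#' @param aln a [dna_alignment()].
#' @return character vector of taxon labels with data.
#' @export
taxa_with_data <- function(aln) {
  has <- apply(aln$seq, 1L, function(r) any(r %in% .base_chars))
  rownames(aln$seq)[has]
}

#' Read and write FASTA alignments
#'
#' Thin wrappers around Biostrings' FASTA parser that validate the result as
#' an alignment: equal-length rows, unique labels, and only DNA/IUPAC/gap
#' characters. Labels are the FASTA identifiers up to the first whitespace.
#' Writing then reading a valid alignment returns an identical object.
#'
#' @param path file path.
#' @return [read_fasta()] returns a [dna_alignment()].
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  labs <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- labs
  if (anyDuplicated(labs))
    stop("duplicate taxon labels in ", path, ": ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  dna_alignment(seqs)
}

#' @param aln a [dna_alignment()].
#' @rdname read_fasta
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  seqs <- apply(aln$seq, 1L, paste0, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- rownames(aln$seq)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Gene partitions: RAxML-style partition files
#'
#' On disk, partitions use 1-based inclusive coordinates in lines of the form
#' `DNA, rbcL = 1-1467`. Internally they are stored 0-based half-open
#' (`start`, `end`), so the example becomes `start = 0`, `end = 1467`.
#'
#' @param path file path.
#' @param n_sites optional alignment length used to validate intervals.
#' @return a `data.frame` with columns `name`, `start`, `end`.
#' @export
read_partitions <- function(path, n_sites = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines,
                  regexec("^DNA\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)$",
                          lines))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed partition line: '", lines[which(bad)[1L]], "'")
  parts <- data.frame(
    name = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)) - 1L,
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  validate_partitions(parts, n_sites)
  parts
}

#' @param partitions partition `data.frame` (internal 0-based half-open).
#' @rdname read_partitions
#' @export
write_partitions <- function(partitions, path) {
  lines <- sprintf("DNA, %s = %d-%d", partitions$name,
                   partitions$start + 1L, partitions$end)
  writeLines(lines, path)
  invisible(path)
}

validate_partitions <- function(parts, n_sites = NULL) {
  stopifnot(all(c("name", "start", "end") %in% names(parts)))
  if (anyDuplicated(parts$name))
    stop("duplicate partition names: ",
         paste(unique(parts$name[duplicated(parts$name)]), collapse = ", "))
  if (any(parts$start < 0L) || any(parts$start >= parts$end))
    stop("partition intervals must satisfy 0 <= start < end")
  if (!is.null(n_sites) && any(parts$end > n_sites))
    stop("partition exceeds alignment length ", n_sites)
  o <- order(parts$start)
  s <- parts$start[o]; e <- parts$end[o]
  if (any(s[-1L] < e[-length(e)])) stop("partitions overlap")
  invisible(parts)
}

#' @rdname read_partitions
#' @param aln a [dna_alignment()].
#' @export
set_partitions <- function(aln, partitions) {
  validate_partitions(partitions, aln_nsites(aln))
  aln$partitions <- partitions[order(partitions$start), , drop = FALSE]
  rownames(aln$partitions) <- NULL
  aln
}

#' Extract one gene from a partitioned alignment
#'
#' @param aln a [dna_alignment()] with partitions.
#' @param gene gene (partition) name.
#' @param drop_missing drop taxa whose row for this gene is entirely
#'   gap/missing (the taxon does not have the gene).
#' @return a [dna_alignment()] of the gene block.
#' @export
extract_gene <- function(aln, gene, drop_missing = TRUE) {
  p <- aln$partitions
  if (is.null(p)) stop("alignment has no partitions")
  i <- match(gene, p$name)
  if (is.na(i)) stop("unknown gene: ", gene)
  g <- aln_subset_cols(aln, (p$start[i] + 1L):p$end[i])
  if (drop_missing) {
    keep <- taxa_with_data(g)
    if (length(keep) < 2L) stop("gene ", gene, " has data for <2 taxa")
    g$seq <- g$seq[keep, , drop = FALSE]
  }
  g
}

#' @rdname extract_gene
#' @param ... passed to `extract_gene()`.
#' @return `split_genes()` returns a named list of per-gene alignments.
#' @export
split_genes <- function(aln, ...) {
  p <- aln$partitions
  if (is.null(p)) stop("alignment has no partitions")
  setNames(lapply(p$name, function(g) extract_gene(aln, g, ...)), p$name)
}
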