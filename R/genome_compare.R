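#' Read a plastid genome summary table
#'
#' Parses a TSV of per-taxon genome statistics (family, species, genome
#' size, GC%, and feature counts). Values prefixed with `>=` (or the
#' typographic `≥`) are lower bounds from draft (incomplete) genomes;
#' such rows are flagged `complete = FALSE` and are excluded from size
#' comparisons. Thousands separators (spaces or commas) are stripped.
#'
#' A transcription of a published Nemaliales chloroplast table ships with
#' the package: `system.file("extdata", "nemaliales_genomes.tsv",
#' package = "chlorophylo")`.
#'
#' @param path TSV file with columns `family`, `species`,
#'   `genome_size_bp`, `gc_pct`, `protein_coding_genes`, `orfs`, `trna`,
#'   `tmrna`, `rrna`, `ncrna`, `introns` (extra columns are kept as-is).
#' @return a `data.frame` of class `genome_table` with numeric columns and
#'   a logical `complete` column.
#' @export
read_genome_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  need <- c("family", "species", "genome_size_bp", "protein_coding_genes")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("genome table lacks columns: ", paste(missing_cols, collapse = ", "))
  numcols <- setdiff(names(raw), c("family", "species", "accession",
                                   "specimen_id", "origin"))
  incomplete <- rep(FALSE, nrow(raw))
  for (cn in numcols) {
    v <- trimws(raw[[cn]])
    lb <- grepl("^(>=|≥)", v)
    v <- sub("^(>=|≥)\\s*", "", v)
    v[v %in% c("-", "", "NA")] <- NA
    v <- gsub("[ ,]", "", v)
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("malformed value '%s' in column '%s', row %d (%s)",
                   raw[[cn]][bad[1L]], cn, bad[1L], raw$species[bad[1L]]))
    raw[[cn]] <- num
    incomplete <- incomplete | lb
  }
  raw$complete <- !incomplete
  class(raw) <- c("genome_table", "data.frame")
  raw
}

#' Write a genome table
#'
#' Inverse of [read_genome_table()]: lower-bound values of incomplete rows
#' are re-prefixed with `>=` so a round trip preserves the flags.
#'
#' @param records a `genome_table`.
#' @param path output TSV path.
#' @export
write_genome_table <- function(records, path) {
  out <- as.data.frame(records)
  numcols <- setdiff(names(out), c("family", "species", "accession",
                                   "specimen_id", "origin", "complete"))
  for (cn in numcols) {
    v <- out[[cn]]
    s <- ifelse(is.na(v), "-",
                ifelse(out$complete, format(v, scientific = FALSE,
                                            trim = TRUE),
                       paste0(">=", format(v, scientific = FALSE,
                                           trim = TRUE))))
    out[[cn]] <- s
  }
  out$complete <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genome size range among complete genomes
#'
#' @param records a `genome_table`.
#' @param families optional family subset (e.g. the ingroup families).
#' @return list with the `min` and `max` record (one-row data.frames) and
#'   `difference` in bp, computed over complete records only.
#' @export
size_summary <- function(records, families = NULL) {
  d <- as.data.frame(records)
  if (!is.null(families)) d <- d[d$family %in% families, , drop = FALSE]
  d <- d[d$complete, , drop = FALSE]
  if (nrow(d) < 2L)
    stop("need at least 2 complete records for a size comparison")
  i_min <- which.min(d$genome_size_bp)
  i_max <- which.max(d$genome_size_bp)
  list(min = d[i_min, , drop = FALSE], max = d[i_max, , drop = FALSE],
       difference = d$genome_size_bp[i_max] - d$genome_size_bp[i_min])
}

#' Read a per-taxon gene content table
#'
#' TSV with columns `taxon`, `gene`, `copies`, `status`
#' (`present`/`pseudogene`/`absent`). A synthetic reconstruction of the
#' Nemaliales gene-content pattern built from a published description (not
#' deposited data) ships as
#' `system.file("extdata", "nemaliales_gene_content_synthetic.tsv",
#' package = "chlorophylo")`.
#'
#' @param path TSV path.
#' @return a `data.frame` with the four columns.
#' @export
read_gene_content <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "gene", "copies", "status")
  if (!all(need %in% names(d)))
    stop("gene content table needs columns: ", paste(need, collapse = ", "))
  if (!all(d$status %in% c("present", "pseudogene", "absent")))
    stop("status must be present/pseudogene/absent")
  d$copies <- as.integer(d$copies)
  if (anyNA(d$copies) || any(d$copies < 0))
    stop("copies must be non-negative integers")
  d
}

#' Gene presence/absence and copy-number matrix
#'
#' Builds a taxon-by-gene copy-count matrix. Pseudogenes count as absent
#' (copy 0) in the matrix but are reported separately. The summary lists
#' genes absent from at least one taxon.
#'
#' @param content gene content `data.frame` from [read_gene_content()].
#' @param gene_set genes (columns) to include; default all genes in
#'   `content`. An empty `gene_set` yields an empty matrix.
#' @return a list of class `gene_presence`: `counts` (integer matrix),
#'   `pseudogenes` (data.frame), `absent` (named list: gene -> taxa
#'   lacking it).
#' @export
presence_absence_matrix <- function(content, gene_set = NULL) {
  taxa <- unique(content$taxon)
  if (is.null(gene_set)) gene_set <- unique(content$gene)
  counts <- matrix(0L, length(taxa), length(gene_set),
                   dimnames = list(taxa, gene_set))
  keep <- content$gene %in% gene_set & content$status == "present"
  for (i in which(keep))
    counts[content$taxon[i], content$gene[i]] <- content$copies[i]
  pseudo <- content[content$gene %in% gene_set &
                      content$status == "pseudogene",
                    c("taxon", "gene"), drop = FALSE]
  absent <- list()
  for (g in gene_set) {
    miss <- rownames(counts)[counts[, g] == 0L]
    if (length(miss)) absent[[g]] <- miss
  }
  structure(list(counts = counts, pseudogenes = pseudo, absent = absent),
            class = "gene_presence")
}

#' @export
print.gene_presence <- function(x, ...) {
  cat(sprintf("gene presence matrix: %d taxa x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  if (length(x$absent)) {
    cat("genes absent in >=1 taxon:\n")
    for (g in names(x$absent))
      cat(sprintf("  %s: %s\n", g, paste(x$absent[[g]], collapse = ", ")))
  } else cat("no gene is absent from any taxon\n")
  if (nrow(x$pseudogenes))
    cat(sprintf("pseudogenes: %s\n",
                paste(sprintf("%s (%s)", x$pseudogenes$gene,
                              x$pseudogenes$taxon), collapse = "; ")))
  invisible(x)
}
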