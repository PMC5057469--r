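#' Non-parametric bootstrap of alignment columns
#'
#' Samples columns with replacement up to the original alignment length
#' (the classical bootstrap replicate). Deterministic for a given seed.
#'
#' @param aln a [dna_alignment()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [dna_alignment()] with the same taxa and length.
#' @export
bootstrap_alignment <- function(aln, seed = NULL) {
  subsample_columns(aln, aln_nsites(aln), seed)
}

#' Subsample alignment columns to a fixed size
#'
#' Draws `size` columns with replacement, producing bootstrap-style
#' pseudo-alignments of arbitrary (smaller or equal) size. Sizes beyond the
#' original alignment length are refused: the experiment never extrapolates
#' beyond the data actually observed.
#'
#' @param aln a [dna_alignment()].
#' @param size number of columns to draw (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [dna_alignment()] with `size` columns.
#' @export
subsample_columns <- function(aln, size, seed = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- aln_nsites(aln)
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  if (size > n)
    stop("size (", size, ") exceeds the alignment length (", n,
         "); subsampling does not extrapolate beyond the original data")
  cols <- if (is.null(seed)) sample.int(n, size, replace = TRUE) else
    with_seed(seed, sample.int(n, size, replace = TRUE))
  aln_subset_cols(aln, cols)
}
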