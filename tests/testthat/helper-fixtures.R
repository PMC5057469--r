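# small fixtures built in code

make_aln <- function(...) dna_alignment(c(...))

# random alignment of pure ACGT with optional gap fraction
rand_aln <- function(n_taxa, n_sites, seed = 1, gap_prob = 0) {
  chars <- chlorophylo:::with_seed(seed, {
    x <- sample(c("A", "C", "G", "T"), n_taxa * n_sites, replace = TRUE)
    if (gap_prob > 0)
      x[runif(length(x)) < gap_prob] <- "-"
    x
  })
  m <- matrix(chars, n_taxa, n_sites,
              dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  dna_alignment(m)
}

jc_model <- function(k = 1L)
  gtr_model(rep(1, 6), rep(0.25, 4), alpha = 1, n_categories = k)

test_model <- function(alpha = 0.6, k = 4L)
  gtr_model(c(1.2, 3, 0.8, 1.1, 4, 1), c(0.3, 0.2, 0.2, 0.3),
            alpha = alpha, n_categories = k)

# a fixed small tree over taxa t1..tn
small_tree <- function(n, seed = 1, total = 1)
  generate_tree(n, total, seed = seed)

# convert a dna_alignment to phangorn's phyDat (for cross-check oracles)
as_phydat <- function(aln) {
  m <- tolower(aln$seq)
  phangorn::phyDat(m, type = "DNA")
}
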