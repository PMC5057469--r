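test_that("occupancy filtering keeps genes present in enough taxa", {
  gene_with_n_taxa <- function(n) {
    m <- matrix("A", 8, 10, dimnames = list(paste0("t", 1:8), NULL))
    if (n < 8) m[(n + 1):8, ] <- "-"
    dna_alignment(m)
  }
  genes <- list(six = gene_with_n_taxa(6), seven = gene_with_n_taxa(7),
                all = gene_with_n_taxa(8))
  kept <- filter_genes_by_taxa(genes)  # default: more than 6 taxa
  expect_named(kept, c("seven", "all"))
  expect_length(filter_genes_by_taxa(list()), 0L)
  expect_named(filter_genes_by_taxa(genes, min_taxa = 1L),
               c("six", "seven", "all"))
})

test_that("concatenation tracks intervals and gap-fills absent taxa", {
  g1 <- rand_aln(4, 100, seed = 1)
  g2 <- rand_aln(4, 200, seed = 2)
  cc <- concatenate(list(a = g1, b = g2))
  expect_equal(aln_nsites(cc), 300L)
  expect_equal(cc$partitions$start, c(0L, 100L))
  expect_equal(cc$partitions$end, c(100L, 300L))

  one <- concatenate(list(solo = g1))
  expect_identical(one$seq, g1$seq)
  expect_equal(nrow(one$partitions), 1L)

  g3 <- make_aln(u = "AAAA", v = "CCCC")
  g4 <- make_aln(w = "GG", x = "TT")
  disj <- concatenate(list(p = g3, q = g4))
  expect_equal(sort(aln_taxa(disj)), c("u", "v", "w", "x"))
  expect_true(all(disj$seq["u", 5:6] == "-"))
  expect_true(all(disj$seq["w", 1:4] == "-"))
})

test_that("variable/informative counts follow their definitions", {
  aln <- make_aln(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")
  expect_equal(count_variable_sites(aln), 0L)
  expect_equal(count_parsimony_informative(aln), 0L)

  # A,A,C,C variable + informative; A,A,A,C variable only; gaps ignored
  aln2 <- make_aln(a = "AA-", b = "AAC", c = "CAN", d = "CC-")
  expect_equal(count_variable_sites(aln2), 2L)
  expect_equal(count_parsimony_informative(aln2), 1L)
})

test_that("counts equal a brute-force per-column oracle on random fixtures", {
  for (seed in c(3, 4, 5)) {
    aln <- rand_aln(6, 50, seed = seed, gap_prob = 0.15)
    aln$seq[aln$seq == "-"][1:5] <- "N"
    counts <- oracle_site_counts(aln)
    expect_equal(count_variable_sites(aln), unname(counts["variable"]))
    expect_equal(count_parsimony_informative(aln),
                 unname(counts["informative"]))
    s <- summarize_alignment(aln)
    expect_equal(s$pct_variable, 100 * counts[["variable"]] / 50)
  }
})

test_that("gene slices summarize the same inside and outside a concatenation", {
  genes <- list(g1 = rand_aln(5, 120, seed = 6),
                g2 = rand_aln(5, 80, seed = 7))
  cc <- concatenate(genes)
  for (g in names(genes)) {
    direct <- summarize_alignment(genes[[g]])
    sliced <- summarize_alignment(extract_gene(cc, g))
    expect_equal(sliced$n_variable, direct$n_variable)
    expect_equal(sliced$n_parsimony_informative,
                 direct$n_parsimony_informative)
  }
})

test_that("percentages guard division by zero and honour both display conventions", {
  s <- alignment_percentages(100, 0, 0)
  expect_equal(s$pct_informative_of_variable, 0)
  expect_true(s$no_variation)
  expect_equal(format_percent(47.77, 1, "trunc"), "47.7")
  expect_equal(format_percent(47.77, 1, "round"), "47.8")
  expect_equal(format_percent(59.36, 1, "trunc"), "59.3")
  expect_equal(format_percent(88.087, 0, "round"), "88")
})
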