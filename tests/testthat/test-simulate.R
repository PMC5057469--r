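test_that("guide trees have the requested size, length and determinism", {
  tr3 <- generate_tree(3, 1.5, seed = 1)
  expect_equal(length(tr3$tip.label), 3L)
  expect_equal(nrow(tr3$edge), 3L)
  expect_equal(tree_length(tr3), 1.5, tolerance = 1e-9)
  t_a <- generate_tree(10, 2, seed = 99)
  t_b <- generate_tree(10, 2, seed = 99)
  expect_true(ape::all.equal.phylo(t_a, t_b))
  expect_equal(tree_length(generate_tree(22, 2.0, seed = 5)), 2.0,
               tolerance = 1e-9)
})

test_that("a zero-rate gene is constant and frequencies match at stationarity", {
  tr <- small_tree(6, seed = 2)
  m <- test_model()
  g0 <- simulate_gene(tr, gene_profile("g", 300, 0, m), seed = 3)
  expect_true(all(apply(g0$seq, 2, function(col)
    length(unique(col)) == 1L)))

  g <- simulate_gene(tr, gene_profile("g", 50000, 1, m), seed = 4)
  obs <- empirical_base_freqs(g)
  expect_true(all(abs(obs - m$base_freqs) < 0.01))
})

test_that("pairwise divergence grows with the rate multiplier", {
  tr <- small_tree(8, seed = 6, total = 0.8)
  m <- test_model()
  mean_pdiff <- function(mult) {
    g <- simulate_gene(tr, gene_profile("g", 4000, mult, m), seed = 11)
    d <- 0; n <- 0
    taxa <- aln_taxa(g)
    for (i in seq_along(taxa)) for (j in seq_len(i - 1L)) {
      d <- d + mean(g$seq[i, ] != g$seq[j, ]); n <- n + 1
    }
    d / n
  }
  p <- vapply(c(0.5, 1, 2), mean_pdiff, 0)
  expect_true(all(diff(p) > 0))
})

test_that("simulated datasets are dimensioned and book-kept consistently", {
  cfg <- sim_config(n_taxa = 6, n_genes = 3, gene_lengths = c(300, 600, 900),
                    seed = 77)
  ds <- simulate_dataset(cfg)
  expect_equal(aln_nsites(ds$alignment), 1800L)
  expect_equal(nrow(ds$alignment$partitions), 3L)
  expect_equal(ds$alignment$partitions$end - ds$alignment$partitions$start,
               c(300L, 600L, 900L))
  expect_equal(nrow(ds$profiles), 3L)
  expect_equal(sort(aln_taxa(ds$alignment)), sort(ds$tree$tip.label))
  # deterministic in the seed
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$alignment$seq, ds2$alignment$seq)

  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- read_fasta(file.path(d, "alignment.fasta"))
  expect_identical(back$seq[aln_taxa(ds$alignment), ], ds$alignment$seq)
  expect_equal(read_partitions(file.path(d, "partitions.txt")),
               ds$alignment$partitions, ignore_attr = TRUE)
  tr <- read_newick(file.path(d, "tree.nwk"))
  expect_setequal(bipartitions(tr), bipartitions(ds$tree))
})

test_that("the full-scale default configuration lands near 145 kb", {
  prof <- draw_gene_profiles(sim_config(seed = 42))
  expect_equal(nrow(prof), 195L)
  total <- sum(prof$length)
  expect_lt(abs(total - 145410) / 145410, 0.10)
  # rate multipliers span roughly an order of magnitude
  qs <- quantile(prof$rate_multiplier, c(0.05, 0.95))
  expect_gt(qs[[2]] / qs[[1]], 5)
  expect_lt(qs[[2]] / qs[[1]], 30)
})

test_that("ML estimation on a long single-gene simulation recovers tree and lengths", {
  tr <- generate_tree(12, 1.8, seed = 13, bl_heterogeneity = 0)
  # keep internal branches comfortably identifiable for the round-trip
  m <- test_model(alpha = 0.9)
  g <- simulate_gene(tr, gene_profile("g", 50000, 1, m), seed = 14)
  ml <- search_ml_tree(g, m, n_starts = 1, seed = 15)
  expect_setequal(bipartitions(ml), bipartitions(tr))
  # branch lengths via patristic distances, robust to edge ordering
  d_true <- ape::cophenetic.phylo(tr)
  d_est <- ape::cophenetic.phylo(ml)[rownames(d_true), colnames(d_true)]
  rel <- abs(d_est - d_true) / pmax(d_true, 1e-6)
  expect_lt(mean(rel[upper.tri(rel)]), 0.15)
})
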