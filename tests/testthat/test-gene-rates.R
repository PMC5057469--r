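# shared small simulated dataset for rate tests
rate_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- test_model(alpha = 0.9)
      tr <- generate_tree(12, 1.6, seed = 61, bl_heterogeneity = 0.6)
      genes <- list(
        slowg = simulate_gene(tr, gene_profile("slowg", 3000, 0.5, m), 62),
        midg  = simulate_gene(tr, gene_profile("midg", 3000, 1.0, m), 63),
        fastg = simulate_gene(tr, gene_profile("fastg", 5000, 2.0, m), 64)
      )
      aln <- concatenate(genes)
      fit <- optimize_branch_lengths(aln, tr, m, tol = 1e-4)
      cache <<- list(m = m, tr = fit, aln = aln, genes = genes)
    }
    cache
  }
})

test_that("the whole concatenation has relative rate 1 and known multipliers are recovered", {
  fx <- rate_fixture()
  self <- relative_gene_rate(fx$aln, fx$tr, fx$m, name = "self")
  expect_equal(self$relative_rate, 1, tolerance = 0.02)

  recs <- relative_gene_rates(fx$aln, fx$tr, fx$m)
  expect_equal(recs$gene, c("slowg", "midg", "fastg"))
  expect_true(all(recs$computable))
  fast <- recs$relative_rate[recs$gene == "fastg"]
  slow <- recs$relative_rate[recs$gene == "slowg"]
  # multiplier 2 gene, relative to the mixed concatenation, sits near
  # 2 / weighted-mean-multiplier; compare against the known generating ratio
  wmean <- sum(c(0.5, 1, 2) * c(3000, 3000, 5000)) / 11000
  expect_equal(fast, 2 / wmean, tolerance = 0.1)
  expect_lt(slow, fast)
  # length-weighted mean of relative rates ~ 1 on complete-taxon data
  expect_equal(sum(recs$relative_rate * recs$length) / sum(recs$length), 1,
               tolerance = 0.1)
})

test_that("genes with too few taxa are flagged uncomputable", {
  fx <- rate_fixture()
  g <- fx$genes$midg
  g$seq[4:12, ] <- "-"  # only 3 taxa left
  rec <- relative_gene_rate(g, fx$tr, fx$m, name = "sparse")
  expect_false(rec$computable)
  expect_true(is.na(rec$relative_rate))
})

test_that("missing taxa are pruned and compared against the pruned concatenated tree", {
  fx <- rate_fixture()
  full <- relative_gene_rate(fx$genes$midg, fx$tr, fx$m, name = "full")
  g <- fx$genes$midg
  g$seq[c("t1", "t2"), ] <- "-"
  rec <- relative_gene_rate(g, fx$tr, fx$m, name = "pruned")
  expect_true(rec$computable)
  expect_equal(rec$n_taxa, 10L)
  pruned <- ape::drop.tip(fx$tr, c("t1", "t2"))
  expect_equal(rec$concat_tree_length, tree_length(pruned))
  # pruning should not bias the ratio relative to the full-taxon estimate
  expect_equal(rec$relative_rate, full$relative_rate, tolerance = 0.15)
})

test_that("categorization applies the length filter and closed-boundary thresholds", {
  recs <- data.frame(
    gene = letters[1:6],
    length = c(799L, 1000L, 1000L, 1000L, 1000L, 1000L),
    n_taxa = 10L, gene_tree_length = 1, concat_tree_length = 1,
    relative_rate = c(1, 0.5, 1.0, 2.0, 0.75, 1.5),
    computable = TRUE)
  out <- categorize_genes(recs)
  expect_equal(as.character(out$category),
               c("excluded", "slow", "medium", "fast", "medium", "medium"))
  # uncomputable genes are excluded regardless of length
  recs$computable[2] <- FALSE
  expect_equal(as.character(categorize_genes(recs)$category)[2], "excluded")
})

test_that("category concatenation collects exactly the member genes", {
  g <- list(a = rand_aln(4, 1000, seed = 1), b = rand_aln(4, 1000, seed = 2),
            c = rand_aln(4, 1000, seed = 3))
  recs <- data.frame(gene = c("a", "b", "c"), length = 1000L, n_taxa = 4L,
                     gene_tree_length = 1, concat_tree_length = 1,
                     relative_rate = c(0.5, 0.6, 2), computable = TRUE)
  recs <- categorize_genes(recs)
  slow <- concatenate_category(g, recs, "slow")
  expect_equal(aln_nsites(slow), 2000L)
  expect_equal(slow$partitions$name, c("a", "b"))
  one <- concatenate_category(g, recs, "fast")
  expect_identical(one$seq, g$c$seq)
  expect_error(concatenate_category(g, recs, "medium"), "no genes")
})
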