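test_that("column subsampling has the right size, provenance and determinism", {
  aln <- rand_aln(4, 10, seed = 1)
  s1 <- subsample_columns(aln, 6, seed = 3)
  expect_equal(aln_nsites(s1), 6L)
  expect_equal(aln_taxa(s1), aln_taxa(aln))
  # every column is a copy of an original column
  orig <- apply(aln$seq, 2, paste0, collapse = "")
  drawn <- apply(s1$seq, 2, paste0, collapse = "")
  expect_true(all(drawn %in% orig))
  expect_identical(subsample_columns(aln, 6, seed = 3)$seq, s1$seq)
  expect_error(subsample_columns(aln, 11, seed = 1), "extrapolate")
  expect_error(subsample_columns(aln, 0), ">= 1")

  one_col <- dna_alignment(rbind(a = "A", b = "C"))
  expect_identical(bootstrap_alignment(one_col, 5)$seq, one_col$seq)
})

test_that("columns are drawn uniformly (binomial check)", {
  aln <- rand_aln(3, 10, seed = 2)
  # distinct columns so provenance is identifiable
  aln$seq[1, ] <- c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C")
  aln$seq[2, ] <- c("A", "A", "C", "C", "G", "G", "T", "T", "A", "A")
  aln$seq[3, ] <- c("A", "C", "A", "C", "A", "C", "A", "C", "G", "G")
  orig <- apply(aln$seq, 2, paste0, collapse = "")
  expect_equal(anyDuplicated(orig), 0L)
  # frequency of each column across many replicates
  reps <- derive_seeds(13, 1000)
  hits <- integer(10)
  for (s in reps) {
    d <- subsample_columns(aln, 10, seed = s)
    hits <- hits + tabulate(match(apply(d$seq, 2, paste0, collapse = ""),
                                  orig), 10)
  }
  p_hat <- hits / sum(hits)
  se <- sqrt(0.1 * 0.9 / sum(hits))
  expect_true(all(abs(p_hat - 0.1) < 3 * se + 1e-9))
})

test_that("support summaries respect their ordering invariant and degeneracies", {
  ref <- ape::read.tree(text = "((a,b),(c,d),e);")
  sup <- c(100, 95, 80, 100)
  prop_ge90 <- mean(sup > 90); prop_eq100 <- mean(sup == 100)
  expect_lte(prop_eq100, prop_ge90)

  # constant alignment: no signal, supports collapse
  m <- matrix("A", 8, 400, dimnames = list(paste0("t", 1:8), NULL))
  aln <- dna_alignment(m)
  ref8 <- small_tree(8, seed = 1)
  res <- support_for_size(aln, ref8, jc_model(1), size = 200, n_boot = 8,
                          seed = 21)
  expect_lte(res$prop_ge90, 0.2)
  expect_lte(res$prop_eq100, res$prop_ge90)
})

test_that("the experiment grid is complete, deterministic and well-formed", {
  tr <- small_tree(8, seed = 31, total = 1)
  m <- test_model(alpha = 1)
  g <- simulate_gene(tr, gene_profile("g", 1500, 1, m), seed = 32)
  curve <- data_requirement_curve(g, tr, m, sizes = c(200, 600),
                                  n_replicates = 2, n_boot = 5, seed = 33)
  expect_equal(nrow(curve$summary), 4L)
  expect_equal(sort(unique(curve$summary$size)), c(200L, 600L))
  expect_true(all(curve$summary$prop_eq100 <= curve$summary$prop_ge90))
  expect_true(all(curve$supports$support >= 0 &
                    curve$supports$support <= 100))
  # full determinism from the top-level seed
  curve2 <- data_requirement_curve(g, tr, m, sizes = c(200, 600),
                                   n_replicates = 2, n_boot = 5, seed = 33)
  expect_identical(curve$summary, curve2$summary)
  expect_identical(curve$supports, curve2$supports)
  s <- summary(curve)
  expect_true(all(c("mean_prop_ge90", "range_prop_ge90") %in% names(s)))
})

test_that("category curves validate their inputs and respect alignment lengths", {
  tr <- small_tree(6, seed = 41)
  m <- jc_model(4)
  g <- simulate_gene(tr, gene_profile("g", 800, 1, m), seed = 42)
  expect_error(
    category_requirement_curves(list(g), tr, m, sizes = 200),
    "named")
  expect_error(
    category_requirement_curves(list(slow = NULL), tr, m, sizes = 200),
    "empty category: 'slow'")
  expect_error(
    category_requirement_curves(list(slow = g), tr, m, sizes = 5000),
    "shorter")
  # identical inputs under identical seeds give overlapping curves
  cc <- category_requirement_curves(list(x = g, y = g), tr, m,
                                    sizes = c(200, 500),
                                    n_replicates = 2, n_boot = 4, seed = 43)
  s <- summary(cc)
  for (sz in c(200, 500)) {
    a <- s[s$source == "x" & s$size == sz, ]
    b <- s[s$source == "y" & s$size == sz, ]
    lo_a <- a$mean_prop_ge90 - a$range_prop_ge90
    hi_a <- a$mean_prop_ge90 + a$range_prop_ge90
    lo_b <- b$mean_prop_ge90 - b$range_prop_ge90
    hi_b <- b$mean_prop_ge90 + b$range_prop_ge90
    expect_true(lo_a <= hi_b && lo_b <= hi_a)  # intervals overlap
  }
})
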