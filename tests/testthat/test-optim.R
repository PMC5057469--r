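test_that("two-taxon optimization reproduces the Jukes-Cantor distance", {
  for (p in c(0.05, 0.12, 0.3)) {
    n <- 3000
    ndiff <- round(n * p)
    aln <- make_aln(
      x = paste(rep("A", n), collapse = ""),
      y = paste(c(rep("C", ndiff), rep("A", n - ndiff)), collapse = ""))
    tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
    fit <- optimize_branch_lengths(aln, tr, jc_model(), tol = 1e-9)
    expect_equal(tree_length(fit), -0.75 * log(1 - 4 * p / 3),
                 tolerance = 1e-4)
  }
})

test_that("identical sequences drive branch lengths to the lower bound", {
  s <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  aln <- make_aln(x = s, y = s, z = s)
  tr <- ape::read.tree(text = "(x:0.1,y:0.2,z:0.1);")
  fit <- optimize_branch_lengths(aln, tr, jc_model())
  expect_true(all(fit$edge.length < 1e-6))
})

test_that("optimization never decreases the log-likelihood", {
  tr <- small_tree(6, seed = 12, total = 1.5)
  m <- test_model()
  g <- simulate_gene(tr, gene_profile("g", 600, 1, m), seed = 3)
  pert <- tr
  pert$edge.length <- pert$edge.length *
    chlorophylo:::with_seed(4, runif(length(pert$edge.length), 0.2, 4))
  ll0 <- log_likelihood(g, pert, m)
  fit <- optimize_branch_lengths(g, pert, m)
  expect_gte(attr(fit, "loglik"), ll0)
  expect_equal(attr(fit, "loglik"), log_likelihood(g, fit, m),
               tolerance = 1e-8)
  # true-tree log-likelihood is attainable from the perturbed start
  expect_gte(attr(fit, "loglik"), log_likelihood(g, tr, m) - 1)
})

test_that("model parameters are recovered from data simulated under known GTR+Gamma", {
  truth <- gtr_model(c(1.3, 3.6, 0.7, 1.4, 5, 1), c(0.34, 0.16, 0.17, 0.33),
                     alpha = 0.9, n_categories = 4)
  tr <- small_tree(12, seed = 21, total = 2.5)
  g <- simulate_gene(tr, gene_profile("g", 50000, 1, truth), seed = 77)
  init <- gtr_model(base_freqs = empirical_base_freqs(g), alpha = 1,
                    n_categories = 4)
  est <- optimize_model_parameters(g, tr, init, optimize_bl = TRUE)
  expect_lt(abs(est$alpha - truth$alpha) / truth$alpha, 0.25)
  expect_true(all(abs(est$base_freqs - truth$base_freqs) < 0.02))
  expect_equal(sum(est$base_freqs), 1, tolerance = 1e-9)
  # fixed point: with the tree held fixed, re-fitting an already-fitted
  # model barely moves the log-likelihood
  tr_est <- attr(est, "tree")
  est_a <- optimize_model_parameters(g, tr_est, est, maxit = 200)
  est_b <- optimize_model_parameters(g, tr_est, est_a, maxit = 200)
  expect_lt(abs(attr(est_b, "loglik") - attr(est_a, "loglik")), 1)
})

test_that("degenerate single-pattern alignments are returned untouched with a warning", {
  aln <- make_aln(a = "AAAA", b = "AAAA", c = "AAAA")
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  m <- test_model()
  expect_warning(out <- optimize_model_parameters(aln, tr, m), "degenerate")
  expect_identical(out, m)
})
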