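test_that("newick reading/writing round-trips topology and lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:0.1,B:0.1):0.05,C:0.1,D:0.1);", f)
  tr <- read_newick(f)
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(nrow(tr$edge), 5L)
  expect_equal(sum(tr$edge.length), 0.45)

  rnd <- small_tree(8, seed = 5)
  write_newick(rnd, f)
  back <- read_newick(f)
  expect_setequal(bipartitions(back), bipartitions(rnd))
  expect_equal(sort(back$edge.length), sort(rnd$edge.length),
               tolerance = 1e-8)

  writeLines("((A,B),(C);", f)
  expect_error(read_newick(f), "parse")
  writeLines("((A,B),C,D);", f)
  expect_warning(tr0 <- read_newick(f), "no branch lengths")
  expect_true(all(tr0$edge.length == 0))
})

test_that("canonicalization makes rotated trees serialize identically", {
  t1 <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1,D:1):0.5,E:3);")
  t2 <- ape::read.tree(text = "(E:3,(D:1,C:1):0.5,(B:2,A:1):0.5);")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_newick(t1, f1); write_newick(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tree length is additive and rooting-invariant", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,C:0.1,D:0.1);")
  expect_equal(tree_length(tr), 0.45)
  expect_equal(tree_length(ape::root(tr, outgroup = "A",
                                     resolve.root = TRUE)), 0.45)
  z <- tr; z$edge.length[] <- 0
  expect_equal(tree_length(z), 0)
})

test_that("bipartitions are canonical and match ape's split counts", {
  tr <- small_tree(9, seed = 8)
  bp <- bipartitions(tr)
  expect_length(bp, 9 - 3)  # n - 3 internal branches
  # invariant under rerooting
  expect_setequal(bp, bipartitions(ape::root(tr, outgroup = "t3",
                                             resolve.root = TRUE)))
})

test_that("bipartition support counts trees containing each split", {
  ref <- ape::read.tree(text = "((A,B),(C,D),E);")
  same <- rep(list(ref), 100)
  s <- bipartition_support(ref, same)
  expect_true(all(s == 100))

  other <- ape::read.tree(text = "((A,C),(B,D),E);")
  s0 <- bipartition_support(ref, rep(list(other), 10))
  expect_true(all(s0 == 0))

  sample4 <- c(rep(list(ref), 3), list(other))
  s75 <- bipartition_support(ref, sample4)
  key_ab <- chlorophylo:::split_key(c("A", "B"), c("C", "D", "E"))
  expect_equal(unname(s75[key_ab]), 75)

  bad <- ape::read.tree(text = "((A,B),(C,F),E);")
  expect_error(bipartition_support(ref, list(bad)), "taxon set")
})

test_that("topology enumeration has the right counts and unique members", {
  expect_length(all_unrooted_topologies(letters[1:4]), 3L)
  tops <- all_unrooted_topologies(letters[1:5])
  expect_length(tops, 15L)
  keys <- vapply(tops, function(t5) paste(sort(bipartitions(t5)),
                                          collapse = "|"), "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(all_unrooted_topologies(letters[1:2]), ">= 3")
})
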