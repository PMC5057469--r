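genome_fixture <- function() {
  read_genome_table(system.file("extdata", "nemaliales_genomes.tsv",
                                package = "chlorophylo"))
}

content_fixture <- function() {
  read_gene_content(system.file("extdata",
                                "nemaliales_gene_content_synthetic.tsv",
                                package = "chlorophylo"))
}

test_that("the genome table parses sizes, bounds and completeness flags", {
  d <- genome_fixture()
  expect_equal(nrow(d), 22L)
  tric <- d[d$species == "Tricleocarpa cylindrica", ]
  expect_false(tric$complete)
  expect_equal(tric$genome_size_bp, 150119)
  noth <- d[d$species == "Nothogenia fastigiata", ]
  expect_true(noth$complete)
  expect_equal(noth$genome_size_bp, 182457)
  expect_equal(noth$protein_coding_genes, 193)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\tspecies\tgenome_size_bp\tprotein_coding_genes",
               "F\tSp one\t12a34\t100"), bad)
  err <- tryCatch(read_genome_table(bad), error = identity)
  expect_match(conditionMessage(err), "12a34")
  expect_match(conditionMessage(err), "genome_size_bp")
})

test_that("genome tables round-trip losslessly, including incompleteness", {
  d <- genome_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genome_table(d, f)
  back <- read_genome_table(f)
  expect_equal(back$complete, d$complete)
  expect_equal(back$genome_size_bp, d$genome_size_bp)
  expect_equal(back$introns, d$introns)
})

test_that("the complete-genome size range reproduces the published difference", {
  d <- genome_fixture()
  s <- size_summary(d)
  expect_equal(s$difference, 8349)
  expect_equal(s$min$species, "Galaxaura rugosa")
  expect_equal(s$max$species, "Liagoropsis maxima")
  # permutation invariance
  s2 <- size_summary(d[rev(seq_len(nrow(d))), ])
  expect_equal(s2$difference, s$difference)
  # all-incomplete input is an error
  expect_error(size_summary(d[!d$complete, ]), "complete")
})

test_that("presence/absence matrix reflects losses, copies and pseudogenes", {
  cont <- content_fixture()
  pam <- presence_absence_matrix(cont)
  expect_equal(dim(pam$counts), c(19L, 12L))
  expect_setequal(pam$absent$pbsA,
                  c("Nothogenia fastigiata", "Trichogloeopsis pedicellata",
                    "Nemalion sp.", "Yamadaella caenomyce"))
  expect_true(all(pam$counts[, "trnM"] == 3L))
  expect_equal(pam$absent$ycf41, "Hommersandiophycus borowitzkae")
  # pseudogenes count as absent but are reported
  expect_true("Nothogenia fastigiata" %in% pam$absent$ycf35)
  expect_true(any(pam$pseudogenes$gene == "ycf21"))
  # core genes are never absent
  expect_null(pam$absent$rbcL)

  empty <- presence_absence_matrix(cont, gene_set = character(0))
  expect_equal(ncol(empty$counts), 0L)
})
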