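test_that("canonical hexamer hits are found on both strands", {
  hits <- scanTargetSites("GGTTAAAAGG")
  expect_equal(hits$position, 3)
  expect_identical(hits$strand, "+")
  expect_equal(hits$mismatches, 0)

  # one substitution away still matches at stringency 1
  hits <- scanTargetSites("TTAAAT")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 1)
  expect_identical(hits$strand, "+")

  # reverse-strand site: forward match of TTTTAA
  hits <- scanTargetSites("GGTTTTAAGG")
  expect_identical(hits$strand, "-")
  expect_equal(hits$position, 3)

  expect_equal(nrow(scanTargetSites("GGGGGG")), 0)
  expect_equal(nrow(scanTargetSites("TTAAAA", maxMismatch = 0)), 1)
})

test_that("N counts as a mismatch, bad letters are located", {
  expect_equal(scanTargetSites("TTANAA")$mismatches, 1)
  expect_equal(nrow(scanTargetSites("TTANAA", maxMismatch = 0)), 0)
  expect_error(scanTargetSites("TTAXAA"), "position 4")
})

test_that("scanner agrees with the brute-force Hamming oracle", {
  set.seed(404)
  bases <- c("A", "C", "G", "T")
  for (i in 1:25) {
    n <- sample(50:400, 1)
    s <- paste(sample(bases, n, replace = TRUE), collapse = "")
    mm <- sample(0:1, 1)
    expect_identical(scanTargetSites(s, mm), bruteHexScan(s, mm),
                     info = paste("seq", i))
  }
  # with N sprinkled in
  for (i in 1:5) {
    s <- paste(sample(c(bases, "N"), 300, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.08)), collapse = "")
    expect_identical(scanTargetSites(s, 1), bruteHexScan(s, 1))
  }
})

test_that("site indexing covers model genes and flags strays", {
  seqs <- c(g1 = "GGTTAAAAGGGGGGG", g2 = "GGGGGGGGGGGGGGG")
  idx <- buildSiteIndex(seqs, c("g1", "g2"))
  expect_equal(unname(siteCounts(idx)), c(1L, 0L))
  expect_equal(totalSites(idx), 1L)
  # zero-site genes stay visible
  expect_named(idx@sites, c("g1", "g2"))

  expect_warning(
    idx2 <- suppressMessages(buildSiteIndex(c(seqs, gX = "GGTTAAAAGG"),
                                            c("g1", "g2"))),
    "not in the model gene set")
  expect_named(idx2@sites, c("g1", "g2"))
  expect_error(buildSiteIndex(character(), c("g1")), "empty")
})

test_that("planted site counts are recovered exactly from FASTA", {
  genes <- paste0("gene", 1:12)
  planted <- stats::setNames(rep(c(0L, 1L, 3L), 4), genes)
  gs <- makeGeneSequences(genes, length = 300,
                          plantedSitesPerGene = planted, seed = 77)
  fa <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(gs$sequences, fa)
  idx <- buildSiteIndex(fa, genes)
  expect_equal(siteCounts(idx)[genes], planted)
  # positions and strands match the generator's record
  for (g in genes) {
    want <- gs$sites[gs$sites$gene == g, c("position", "strand")]
    got <- idx@sites[[g]][, c("position", "strand")]
    expect_equal(got[order(got$position), ],
                 want[order(want$position), ], ignore_attr = TRUE)
  }
})
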