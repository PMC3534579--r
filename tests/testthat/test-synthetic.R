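test_that("toy networks are reproducible and honour the GPR fractions", {
  a <- makeToyNetwork(2, 3, 0.3, 0.2, seed = 99)
  b <- makeToyNetwork(2, 3, 0.3, 0.2, seed = 99)
  expect_identical(metabolites(a$model), metabolites(b$model))
  expect_identical(reactions(a$model), reactions(b$model))
  expect_identical(a$truth, b$truth)

  allIso <- makeToyNetwork(3, 4, 1, 0, seed = 5)
  expect_length(allIso$truth$effectiveGenes, 0)
  expect_gt(length(allIso$truth$bufferedGenes), 0)

  allSole <- makeToyNetwork(1, 3, 0, 0, seed = 5)
  expect_identical(allSole$truth$effectiveGenes, c("g1_1a", "g1_2a"))
  # hand enumeration: g1_1a sits before m1_2 and m1_3; g1_2a before m1_3
  expect_identical(allSole$truth$impacts$g1_1a, c("m1_2", "m1_3"))
  expect_identical(allSole$truth$impacts$g1_2a, "m1_3")
  expect_true(all(c(allSole$truth$effectiveGenes,
                    allSole$truth$bufferedGenes) %in%
                  geneIds(allSole$model)))
})

test_that("planted sequences carry exactly the recorded sites", {
  gs0 <- makeGeneSequences("g1", length = 120, plantedSitesPerGene = 0,
                           seed = 2)
  expect_equal(nrow(scanTargetSites(as.character(gs0$sequences[[1]]))), 0)

  gs3 <- makeGeneSequences("g1", length = 200, plantedSitesPerGene = 3,
                           seed = 3)
  hits <- scanTargetSites(as.character(gs3$sequences[[1]]))
  expect_equal(nrow(hits), 3)
  expect_setequal(hits$position, gs3$sites$position)
  expect_identical(hits$strand[order(hits$position)],
                   gs3$sites$strand[order(gs3$sites$position)])
  expect_true(all(hits$mismatches == 0))

  # determinism
  expect_identical(as.character(gs3$sequences),
                   as.character(makeGeneSequences(
                     "g1", length = 200, plantedSitesPerGene = 3,
                     seed = 3)$sequences))

  expect_error(makeGeneSequences("g1", length = 30,
                                 plantedSitesPerGene = 5, seed = 1))
})

test_that("reverse-strand plants are found as minus-strand sites", {
  set.seed(0)
  found <- FALSE
  for (seed in 1:10) {
    gs <- makeGeneSequences("g1", length = 150, plantedSitesPerGene = 2,
                            seed = seed)
    if (any(gs$sites$strand == "-")) {
      hits <- scanTargetSites(as.character(gs$sequences[[1]]))
      minus <- gs$sites[gs$sites$strand == "-", ]
      expect_true(all(minus$position %in%
                      hits$position[hits$strand == "-"]))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("insertion tables follow the effectiveness bias", {
  toy <- makeToyNetwork(4, 4, 0.5, 0, seed = 13)
  insAll <- makeInsertions(toy$truth, "A", 400, 1, seed = 1)
  expect_true(all(insAll$gene %in% toy$truth$effectiveGenes))

  ins0 <- makeInsertions(toy$truth, "A", 4000, 0, seed = 2)
  tab <- table(factor(ins0$gene, levels = toy$truth$genes))
  # uniform null: chi-square goodness of fit should not blow up
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)

  two <- makeInsertions(toy$truth, c("A", "B"), 5, 0.5, seed = 3)
  expect_equal(table(two$donor)[["A"]], 5)
  expect_equal(table(two$donor)[["B"]], 5)
  expect_identical(two, makeInsertions(toy$truth, c("A", "B"), 5, 0.5,
                                       seed = 3))
})

test_that("disease maps plant a disease only when a pool exists", {
  keys <- paste0("k", 1:20)
  dm <- makeDiseaseMap(keys, 3, 5, plantedKeys = c("k1", "k2"), seed = 4)
  expect_true("planted_disease" %in% dm$disease)
  expect_setequal(dm$metabolite_key[dm$disease == "planted_disease"],
                  c("k1", "k2"))
  expect_identical(attr(dm, "planted"), "planted_disease")
  expect_error(makeDiseaseMap(keys, 3, 5, plantedKeys = character()),
               "empty metabolite pool")
  dm0 <- makeDiseaseMap(keys, 2, 5, seed = 4)
  expect_identical(attr(dm0, "planted"), NA_character_)
  expect_identical(dm0, makeDiseaseMap(keys, 2, 5, seed = 4))
})

test_that("disjoint donor gene pools give zero three-way overlap", {
  toy <- makeToyNetwork(3, 3, 0, 0, seed = 37)
  eff <- toy$truth$effectiveGenes
  byChain <- split(eff, sub("^g(\\d+)_.*", "\\1", eff))
  ins <- do.call(rbind, lapply(seq_along(byChain), function(i)
    data.frame(donor = LETTERS[i], gene = byChain[[i]])))
  scan <- scanInsertions(toy$model, ins)
  expect_true(all(scan@overlaps$overlap == 0))
})
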